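---
title: "Detecting animal call combinations with collocation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting animal call combinations with collocation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colloc)
```

## The problem

Many animals produce two-call combinations — a pair of context-specific
calls uttered in close temporal succession — and some of these combinations
carry meaning beyond their parts. But calls also land next to each other by
chance, simply because both are common, so the raw frequency of a pair says
little. Treating a set of recorded call pairs as a *corpus*, in the sense of
corpus linguistics, lets us borrow the standard machinery for separating
genuine collocations ("drink coffee") from happenstance juxtapositions: we
compare how often two calls co-occur with how often each combines with
everything else.

`colloc` implements the two collocation statistics most useful at the
bigram (two-unit) level, a generator for synthetic test corpora with known
planted structure, and the file plumbing to run both analyses from R or a
shell.

## The data model

The unit of analysis is the **bigram token**: one ordered pair of call
labels (first slot, second slot). A corpus is a multiset of such tokens,
supplied either directly as a pair list (`first,second[,count]`) or as
longer call sequences from which adjacent pairs are extracted. From a corpus,
`tabulate_bigrams()` builds the square count matrix and its marginals:

* `f_first(e)` — how often call `e` occupies the first slot (row sums);
* `f_second(e)` — second slot (column sums);
* `f_token(e) = f_first(e) + f_second(e)` — token frequency;
* `n_pairs` — total bigram tokens; `n_calls = 2 * n_pairs` — total call
  tokens in a pure bigram corpus.

Self-pairs (A,A) are allowed; each of their two tokens is counted once, so
the identity `sum(f_token) = n_calls` always holds exactly. Labels are
case-sensitive and trimmed of surrounding whitespace. For sequence input
the default window is *adjacent overlapping* (a sequence A,B,C yields
(A,B) and (B,C)); a disjoint window is available, and the two coincide for
pair-list input. The package deliberately takes pre-segmented data: what
temporal gap makes two calls "a combination" is a field decision that
happens before the statistics, not inside them.

## MDCA: signed binomial tail probabilities

Multiple Distinctive Collocation Analysis scores every *ordered* pair
(a, b) with an exact binomial model. Writing `k = counts[a, b]`,
`n = f_first(a)` and `p = f_second(b) / n_pairs`, the chance expectation is
`n * p`, and

* if `k > n p` (attraction): `score = -log10 Pr(X >= k)`, `X ~ Bin(n, p)`;
* if `k < n p` (repulsion): `score = +log10 Pr(X <= k)` (reported
  negative);
* if `k = n p` exactly: the pair is independent and the score is 0.

The magnitude is the familiar "pbin": the p value of an exact test on a
log10 scale, so `|score| > 1.3, 2, 3` corresponds to p < 0.05, 0.01,
0.001 (strict inequalities; `significance_band()` applies them). Because
the test is exact it needs no large-sample assumptions, which is what makes
it usable on the small, skewed corpora typical of animal data. The
orientation — trials from the first call's first-slot frequency, success
probability from the second call's second-slot share — is what ties the
score to call order and powers the linearisation report
(`order_asymmetry()`): a combination is *ordered* if exactly one direction
shows a significant attraction, *bidirectional* if both do.

Three numerical choices matter:

* Tails are cumulative (`Pr(X >= k)`, not the point mass) — the standard
  in distinctive collexeme analysis; on fully exclusive pairs (`k = n`) the
  two coincide.
* Tails are evaluated on the log scale (`pbinom(..., log.p = TRUE)`), so
  scores stay finite for any `p` strictly inside (0, 1) even when the tail
  underflows double precision — a large-exclusive corpus already has tails
  near 1e-25.
* Raw scores are uncorrected for multiplicity, which is how pbins are
  conventionally read; since many pairs are tested at once, `mdca()` also
  emits `band_holm`, the band after Holm adjustment over the family of
  pairs scored in that call. It is strictly more conservative.

## MICA: pointwise mutual information

Mutual Information Collocation Analysis scores *unordered* pairs by the
binary-log ratio of observed to expected frequency:

```
score(a, b) = log2( observed / expected ),
observed    = counts[a, b] + counts[b, a]
expected    = f_token(a) * f_token(b) / n_calls
```

Zero means independence; positive, attraction; negative, repulsion. The
denominator is the *call-token* total, not the pair total — this is what
makes the score exactly invariant to multiplying every count by a constant
(both observed and expected scale linearly), so corpus size changes the
precision of the estimate, never its value. The expectation approximates
the exact mean co-occurrence under random re-pairing of all tokens, which
is `f_token(a) f_token(b) / (n_calls - 1)`; `shuffle_null()` lets you check
this empirically. The logarithm is binary, so scores are bits of shared
information; band labels reuse the pbin convention for continuity of
reporting, but for MI they are a labelling convention, not a calibrated
test.

Mutual information famously *over*-weights rare events: of two equally
exclusive pairs, the rarer one scores higher. For animal corpora this is a
feature — rare but exclusive combinations (alarm sequences, say) are
flagged rather than drowned out. An unobserved pair has no defined MI; it
is reported as `NA` with direction `"not-observed"`, never as `-Inf`, and
no pseudo-count smoothing is applied.

The two statistics are complementary — MDCA grows with sample size,
resolves order, and favours common combinations; MICA is size-invariant,
order-blind, and favours rare exclusive ones — so `colloc_report()` runs
both and ranks pairs by summed rank across the two, ties broken by best
single score then alphabetically, giving a deterministic shortlist of
candidates for follow-up.

## The synthetic generator

`synthetic_spec()` + `simulate_corpus()` create corpora with known ground
truth: a set of *planted* bigrams whose counts are placed exactly (they are
design constants, not sampled rates), an optional uniform random
background, and an integer scale multiplier. Two exclusion policies govern
the background:

* `"planted-pairs"` (default): only the planted *ordered pairs* are removed
  from the background candidates, so planted call types still recombine
  with other partners — the "recombination" regime.
* `"planted-calls"`: every pair touching a planted call is removed, keeping
  planted bigrams fully exclusive against a noisy background — the regime
  for parameter-recovery experiments.

Background candidates are heterotypic (no self-pairs): the design emulates
call types recombining *with other call types*. Draws are uniform with
replacement and fully determined by the spec's seed.

`artificial_corpus()` instantiates the four canonical designs on the
ten-call `default_repertoire()`: three planted bigrams Huff-Puff (4),
Peep-Howl (5) and Howl-Peep (7), crossed over size (x1 or x10) and
recombination (none, or background pairs filling the totals to 49/490).
The exclusive sets SE and LE are fully determined — 16 pairs / 32 calls and
160 / 320 — and reproduce the reference score columns exactly:
Huff-Puff is the rare, strictly ordered combination, Peep-Howl the common
order-flexible one. The recombination backgrounds are seeded random draws
unless an explicit background table is supplied, in which case it is used
verbatim and validated against the expected totals (33 or 330 background
pairs).

What the generator does *not* emulate: acoustic variation and
classification error (labels are taken as given), temporal structure within
bouts beyond adjacency, per-individual or per-context heterogeneity, and
non-uniform background recombination. Passing tests on these corpora show
the statistics behave as designed under their own assumptions; they do not
show robustness to misclassified or autocorrelated field data.

`shuffle_null()` is the matching null model: all `2 * n_pairs` call tokens
are pooled, permuted and re-paired, preserving every `f_token` exactly
while destroying pair structure. It underlies the package's type-I check
(the share of shuffled corpora reaching the p < 0.05 band stays below 10%,
the slack reflecting the discreteness of small-sample binomial tails).

## Problem sizes and tolerances in the test suite

The suite verifies the binomial tails against a naive term-by-term pmf
summation (trial counts <= 25, relative error under 1e-12), the shuffle
null against its closed-form mean over 2000 draws (within four Monte-Carlo
standard errors), planted-bigram recovery over 100 seeded corpora of 205
pairs (requiring at least 95 top-ranked recoveries), background uniformity
aggregated over 50 seeds of 1000 draws (four binomial standard deviations),
and the type-I proportion over 200 shuffles. These sizes make every
stochastic check stable across seeds while keeping the whole suite fast on
one CPU.

## Known limitations

* The binomial orientation cannot be distinguished from its transpose on
  fully exclusive corpora; it is pinned to the reproducible reference
  columns.
* MICA bands are descriptive labels, not p values.
* Scores for pairs whose first call never occupies the first slot are
  undefined in MDCA (no trials); such directions are treated as
  not-significant in the linearisation report rather than imputed.
* No support for trigrams or longer structures: sequence dynamics beyond
  the bigram call for Markov-type models, which are out of scope here.
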