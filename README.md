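# colloc

Collocation analysis for animal call combinations.

Animal calls can land next to each other through chance alone, so the raw
frequency of a two-call combination ("bigram") says little about whether it
is a real, communicatively relevant unit. `colloc` treats a set of recorded
call pairs as a corpus and applies the two collocation statistics of corpus
linguistics that fit the bigram level, flagging pairs that co-occur above
(or below) what each call's overall frequency predicts. It is aimed at
bioacousticians and behavioural ecologists screening vocal data for
candidate call combinations worth experimental follow-up.

## The statistics

For a corpus tabulated into an ordered-pair count matrix with first-slot
marginals `f_first`, second-slot marginals `f_second`, token frequencies
`f_token = f_first + f_second`, pair total `n_pairs` and call-token total
`n_calls = 2 n_pairs`:

**MDCA** (Multiple Distinctive Collocation Analysis) scores each *ordered*
pair (a, b) by an exact binomial tail on a signed log scale. With
`k = counts[a, b]`, `n = f_first(a)`, `p = f_second(b) / n_pairs`:

    score =  -log10 Pr(X >= k),  X ~ Bin(n, p)   if k > n p   (attraction)
    score =  +log10 Pr(X <= k)                   if k < n p   (repulsion, negative)
    score =  0                                   if k = n p   (independent)

`|score| > 1.3 / 2 / 3` reads as p < 0.05 / 0.01 / 0.001. Scores grow with
sample size and respond to call order, so comparing (a, b) with (b, a)
classifies a combination's linearisation.

**MICA** (Mutual Information Collocation Analysis) scores each *unordered*
pair by pointwise mutual information in bits:

    score = log2( observed / expected ),
    observed = counts[a, b] + counts[b, a],
    expected = f_token(a) f_token(b) / n_calls

MICA is exactly invariant to corpus scale and ranks rare exclusive pairs
highest; the two statistics are complementary and `colloc_report()` runs
both.

The package also ships a synthetic-corpus generator (exact planted bigrams
over a uniform recombining background, plus the four canonical artificial
data sets `SE`/`SR`/`LE`/`LR` on a ten-call repertoire), a token-shuffling
permutation null, delimited-text input/output for pair lists and call
sequences, ggplot2 `autoplot()` methods, and a small CLI
(`inst/cli/colloc`) with `simulate` / `tabulate` / `mdca` / `mica` /
`report` subcommands.

## Worked example

```r
library(colloc)

se <- artificial_corpus("SE")   # 16 bigram tokens over 32 calls
mdca(se)
#> # A tibble: 3 × 10
#>   first second observed trials success_prob expected score direction  band
#> 1 Peep  Howl          5      5        0.312     1.56  2.53 attraction p<0.01
#> 2 Howl  Peep          7      7        0.438     3.06  2.51 attraction p<0.01
#> 3 Huff  Puff          4      4        0.25      1     2.41 attraction p<0.01

mica(se)
#> # A tibble: 2 × 7
#>   call_a call_b observed expected score direction  band
#> 1 Huff   Puff          4      0.5  3    attraction p<0.01
#> 2 Howl   Peep         12      4.5  1.42 attraction p<0.05

colloc_report(se)
#> Collocation report: 10 call types, 16 bigram tokens, 32 call tokens
#>
#> Joint ranking (best candidates over both analyses):
#>   1. Huff-Puff  MDCA 2.41  MICA 3  order: ordered
#>   2. Howl-Peep  MDCA 2.53  MICA 1.42  order: bidirectional
```

Reading the numbers: all three planted ordered bigrams attract their
partners at p < 0.01 by MDCA (pbins 2.4-2.5 at 1 dp). MICA collapses
Peep-Howl and Howl-Peep into one combination and scores the rare exclusive
Huff-Puff (4 observed vs 0.5 expected, 3 bits) above the ten-times-commoner
Peep-Howl (12 vs 4.5, 1.4 bits). The linearisation column shows Huff-Puff
occurs in a fixed order while Peep and Howl combine both ways. On the
ten-fold larger `LE` corpus the MDCA scores scale to 24.1 / 25.3 / 25.1
while the MICA scores are unchanged — the size-sensitivity contrast between
the two statistics.

Reading data instead: `read_pairs("pairs.csv")` (header
`first,second[,count]`) or `read_sequences("bouts.csv")` (header
`sequence_id,position,call`) feed the same functions.

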