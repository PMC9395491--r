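#' Specify a synthetic planted-bigram corpus
#'
#' A declarative recipe for a simulated vocal corpus: a set of planted
#' bigrams whose counts are placed exactly (not sampled), an optional random
#' background of additional pairs, a scale multiplier applied to everything,
#' and a seed. This is the design behind the built-in artificial data sets:
#' planting fixed counts probes detection, the background probes robustness
#' to recombination (calls pairing with many partners), and the scale probes
#' sample-size sensitivity.
#'
#' @param repertoire A [repertoire()] (or character vector) of call types.
#' @param planted Data frame with columns `first`, `second`, `count`
#'   (counts >= 1); each ordered pair may appear once.
#' @param background_pairs Number of additional background bigram tokens
#'   (before scaling).
#' @param background_policy `"exclusive"` (no background; `background_pairs`
#'   must be 0), `"recombine-uniform"` (background drawn uniformly over all
#'   heterotypic ordered pairs other than the planted ones, so every call
#'   type recombines with other call types outside the planted
#'   combinations), or `"from-table"` (background given verbatim via
#'   `background_table`).
#' @param background_table For policy `"from-table"`: a pair-list data frame
#'   (`first`, `second`, optional `count`) whose total must equal
#'   `background_pairs`.
#' @param background_exclude For policy `"recombine-uniform"`:
#'   `"planted-pairs"` (default) removes only the planted ordered pairs from
#'   the background candidates, so planted call types still recombine with
#'   other partners (the recombination design); `"planted-calls"` removes
#'   every pair touching a planted call, keeping the planted bigrams fully
#'   exclusive against a recombining background.
#' @param scale Positive integer multiplier applied to planted counts and
#'   background size.
#' @param seed Integer seed; required whenever the background is random.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(default_repertoire(),
#'                planted = data.frame(first = "Huff", second = "Puff", count = 4),
#'                background_pairs = 30, background_policy = "recombine-uniform",
#'                seed = 1)
#' @export
synthetic_spec <- function(repertoire, planted,
                           background_pairs = 0,
                           background_policy = c("exclusive",
                                                 "recombine-uniform",
                                                 "from-table"),
                           background_table = NULL,
                           background_exclude = c("planted-pairs",
                                                  "planted-calls"),
                           scale = 1, seed = NULL) {
  background_policy <- match.arg(background_policy)
  background_exclude <- match.arg(background_exclude)
  rep_labels <- validate_repertoire(unclass(repertoire))
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("first", "second", "count") %in% names(planted)))
  if (any(planted$count < 1) || any(planted$count != round(planted$count))) {
    rlang::abort("Planted counts must be integers >= 1.",
                 class = "colloc_bad_spec")
  }
  key <- paste(planted$first, planted$second, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- planted[duplicated(key), ]
    rlang::abort(paste0("Planted pair duplicated in spec: ",
                        dup$first[1], "-", dup$second[1]),
                 class = "colloc_bad_spec")
  }
  bad <- setdiff(unique(c(planted$first, planted$second)), rep_labels)
  if (length(bad)) {
    rlang::abort(paste0("Planted call label(s) not in repertoire: ",
                        paste(bad, collapse = ", ")),
                 class = "colloc_bad_spec")
  }
  if (background_policy == "exclusive" && background_pairs != 0) {
    rlang::abort("Policy `exclusive` requires background_pairs = 0.",
                 class = "colloc_bad_spec")
  }
  if (background_policy == "recombine-uniform" && background_pairs > 0 &&
      is.null(seed)) {
    rlang::abort("A seed is required when the background is random.",
                 class = "colloc_bad_spec")
  }
  if (background_policy == "from-table") {
    if (is.null(background_table)) {
      rlang::abort("Policy `from-table` requires `background_table`.",
                   class = "colloc_bad_spec")
    }
    background_table <- as_corpus(background_table, repertoire = rep_labels)
    if (nrow(background_table) != background_pairs) {
      rlang::abort(sprintf(
        "`background_table` holds %d pairs but the spec expects %d.",
        nrow(background_table), background_pairs),
        class = "colloc_bad_spec")
    }
  }
  if (scale < 1 || scale != round(scale)) {
    rlang::abort("`scale` must be a positive integer.",
                 class = "colloc_bad_spec")
  }
  structure(list(repertoire = rep_labels, planted = planted,
                 background_pairs = as.integer(background_pairs),
                 background_policy = background_policy,
                 background_table = background_table,
                 background_exclude = background_exclude,
                 scale = as.integer(scale), seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> %d call types, %d planted bigram type(s), ",
                     "%d background pairs (%s), scale x%d, seed %s\n"),
              length(x$repertoire), nrow(x$planted), x$background_pairs,
              x$background_policy, x$scale,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Simulate a corpus from a synthetic spec
#'
#' Planted counts are placed verbatim (times `scale`); background pairs are
#' then drawn according to the spec's policy. Given the same spec and seed
#' the result is identical.
#'
#' @param spec A [synthetic_spec()].
#' @return A `colloc_corpus` with
#'   `scale * (sum(planted counts) + background_pairs)` bigram tokens; the
#'   provenance attribute records the policy and seed.
#' @examples
#' sp <- synthetic_spec(default_repertoire(),
#'                      planted = data.frame(first = "Huff", second = "Puff",
#'                                           count = 4))
#' simulate_corpus(sp)
#' @export
simulate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  planted <- tibble::tibble(
    first = rep(spec$planted$first, spec$planted$count * spec$scale),
    second = rep(spec$planted$second, spec$planted$count * spec$scale))
  n_bg <- spec$background_pairs * spec$scale
  bg <- NULL
  if (n_bg > 0) {
    if (spec$background_policy == "from-table") {
      tabpairs <- spec$background_table
      bg <- tibble::tibble(
        first = rep(tabpairs$first, spec$scale),
        second = rep(tabpairs$second, spec$scale))
    } else {
      labs <- as.character(spec$repertoire)
      cand <- tidyr::expand_grid(first = labs, second = labs)
      cand <- cand[cand$first != cand$second, ]
      if (identical(spec$background_exclude, "planted-calls")) {
        off_limits <- unique(c(spec$planted$first, spec$planted$second))
        cand <- cand[!(cand$first %in% off_limits | cand$second %in% off_limits), ]
      } else {
        key <- paste(cand$first, cand$second, sep = "\r")
        planted_key <- paste(spec$planted$first, spec$planted$second, sep = "\r")
        cand <- cand[!key %in% planted_key, ]
      }
      if (nrow(cand) == 0) {
        rlang::abort("No candidate background pairs outside the planted set.",
                     class = "colloc_bad_spec")
      }
      idx <- withr::with_seed(spec$seed,
                              sample.int(nrow(cand), n_bg, replace = TRUE))
      bg <- cand[idx, ]
    }
  }
  out <- dplyr::bind_rows(planted, bg)
  as_corpus(out, repertoire = spec$repertoire,
            provenance = sprintf("simulate_corpus(policy=%s, scale=%d, seed=%s)",
                                 spec$background_policy, spec$scale,
                                 if (is.null(spec$seed)) "none" else spec$seed))
}

#' The four built-in artificial data sets
#'
#' Reconstructs the four artificial vocal data sets used throughout the
#' package's documentation, crossing corpus size with recombination over the
#' ten-call [default_repertoire()]. All four plant the same three bigrams —
#' Huff-Puff, Peep-Howl and Howl-Peep at counts 4, 5 and 7 (so Huff-Puff is
#' the low-frequency, strictly ordered combination and Peep/Howl the common,
#' order-flexible one):
#'
#' * `SE` (small exclusive): exactly the planted pairs — 16 bigram tokens,
#'   32 calls.
#' * `LE` (large exclusive): `SE` with every count times 10 — 160 / 320.
#' * `SR` (small recombination): planted counts 4/5/7 plus 33 background
#'   pairs in which all call types recombine with other call types outside
#'   the three combinations — 49 pairs, 98 calls.
#' * `LR` (large recombination): planted counts 40/50/70 plus 330 background
#'   pairs — 490 / 980.
#'
#' `SE` and `LE` are fully determined; the recombination backgrounds are
#' drawn uniformly from the seeded generator unless an explicit
#' `background_table` (e.g. a published background distribution) is
#' supplied, in which case it is used verbatim.
#'
#' @param name One of `"SE"`, `"SR"`, `"LE"`, `"LR"`.
#' @param seed Integer seed; required for `SR`/`LR` without a
#'   `background_table`.
#' @param background_table Optional pair-list data frame (or file path
#'   readable by [read_pairs()]) giving the exact background pairs for
#'   `SR`/`LR`; its total must be 33 (SR) or 330 (LR).
#' @return A `colloc_corpus`.
#' @examples
#' artificial_corpus("SE")
#' artificial_corpus("SR", seed = 1)
#' @export
artificial_corpus <- function(name = c("SE", "SR", "LE", "LR"), seed = NULL,
                              background_table = NULL) {
  name <- match.arg(name)
  planted <- tibble::tibble(first = c("Huff", "Peep", "Howl"),
                            second = c("Puff", "Howl", "Peep"),
                            count = c(4L, 5L, 7L))
  scale <- if (name %in% c("LE", "LR")) 10L else 1L
  recomb <- name %in% c("SR", "LR")
  if (!recomb) {
    spec <- synthetic_spec(default_repertoire(), planted, scale = scale)
  } else {
    n_bg <- 33L
    if (!is.null(background_table)) {
      if (is.character(background_table) && length(background_table) == 1) {
        background_table <- read_pairs(background_table)
      }
      background_table <- as_corpus(background_table,
                                    repertoire = default_repertoire())
      expect_bg <- n_bg * scale
      if (nrow(background_table) != expect_bg) {
        rlang::abort(sprintf(
          paste0("Background table for %s holds %d pairs; expected %d ",
                 "(total %d pairs with the planted bigrams)."),
          name, nrow(background_table), expect_bg, expect_bg + 16L * scale),
          class = "colloc_bad_spec")
      }
      spec <- synthetic_spec(default_repertoire(), planted,
                             background_pairs = nrow(background_table),
                             background_policy = "from-table",
                             background_table = background_table,
                             scale = 1)
      spec$planted$count <- spec$planted$count * scale
      scale <- 1L
    } else {
      if (is.null(seed)) {
        rlang::abort(paste0("A seed is required to draw the ", name,
                            " background (or supply `background_table`)."),
                     class = "colloc_bad_spec")
      }
      spec <- synthetic_spec(default_repertoire(), planted,
                             background_pairs = n_bg,
                             background_policy = "recombine-uniform",
                             scale = scale, seed = seed)
    }
  }
  out <- simulate_corpus(spec)
  attr(out, "provenance") <- sprintf("artificial_corpus(%s%s)", name,
                                     if (recomb && !is.null(seed))
                                       paste0(", seed=", seed) else "")
  out
}

#' Permutation null: shuffle call tokens and re-pair
#'
#' Destroys the pair structure of a corpus while preserving every call's
#' token frequency exactly: all 2*n_pairs call tokens are pooled, randomly
#' permuted, and re-paired consecutively. Under this null the expected
#' unordered co-occurrence count of calls a and b is
#' f_token(a) * f_token(b) / (n_calls - 1), which the MICA expectation
#' f_token(a) * f_token(b) / n_calls approximates.
#'
#' @param corpus A `colloc_corpus` (or pair-list data frame); must be
#'   non-empty.
#' @param seed Integer seed.
#' @return A `colloc_corpus` with identical token frequencies and shuffled
#'   pairing.
#' @examples
#' se <- artificial_corpus("SE")
#' shuffle_null(se, seed = 42)
#' @export
shuffle_null <- function(corpus, seed) {
  corpus <- as_corpus(corpus, repertoire = attr(corpus, "repertoire"),
                      provenance = attr(corpus, "provenance"))
  if (nrow(corpus) == 0) {
    rlang::abort("Cannot shuffle an empty corpus.", class = "colloc_bad_input")
  }
  tokens <- c(rbind(corpus$first, corpus$second))
  tokens <- withr::with_seed(seed, sample(tokens))
  odd <- seq(1, length(tokens), by = 2)
  as_corpus(tibble::tibble(first = tokens[odd], second = tokens[odd + 1]),
            repertoire = attr(corpus, "repertoire"),
            provenance = paste0(attr(corpus, "provenance"),
                                " | shuffle_null(seed=", seed, ")"))
}
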