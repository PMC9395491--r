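# Core of the MDCA statistic. For one ordered pair (first, second):
#   k = counts[first, second], n = f_first(first), p = f_second(second)/n_pairs
# and the chance expectation is n*p. Attraction (k > np) is scored as
# -log10 P(X >= k), repulsion (k < np) as the signed -log10 of the lower
# tail, i.e. log10 P(X <= k) < 0. Tails are evaluated on the log scale so
# extreme scores never overflow to Inf for p in (0, 1).
mdca_core <- function(k, n, p) {
  expected <- n * p
  score <- numeric(length(k))
  direction <- rep("independent", length(k))
  eq <- abs(k - expected) < 1e-9
  up <- !eq & k > expected
  lo <- !eq & k < expected
  if (any(up)) {
    score[up] <- -stats::pbinom(k[up] - 1, n[up], p[up],
                                lower.tail = FALSE, log.p = TRUE) / log(10)
    direction[up] <- "attraction"
  }
  if (any(lo)) {
    score[lo] <- stats::pbinom(k[lo], n[lo], p[lo], log.p = TRUE) / log(10)
    direction[lo] <- "repulsion"
  }
  list(expected = expected, score = score, direction = direction)
}

#' Significance bands for pbin scores
#'
#' Maps the magnitude of a signed -log10 score ("pbin") onto the
#' conventional significance labels: |pbin| > 3 is p < 0.001, > 2 is
#' p < 0.01, > 1.3 is p < 0.05, and anything at or below 1.3 is NS.
#' Inequalities are strict, so 1.3 exactly is NS.
#'
#' @param score Numeric vector of signed scores; banding uses `abs(score)`.
#' @return Character vector of band labels.
#' @examples
#' significance_band(c(2.4, -1.5, 0, 1.3))
#' @export
significance_band <- function(score) {
  if (any(!is.finite(score))) {
    rlang::abort("significance_band() needs finite scores.",
                 class = "colloc_bad_input")
  }
  a <- abs(score)
  dplyr::case_when(a > 3 ~ "p<0.001",
                   a > 2 ~ "p<0.01",
                   a > 1.3 ~ "p<0.05",
                   TRUE ~ "NS")
}

#' Multiple Distinctive Collocation Analysis
#'
#' Scores every ordered call pair by a signed -log10 binomial tail
#' probability ("pbin"). For pair (first, second) the binomial has
#' k = observed pair count, n = first-slot frequency of `first`, and success
#' probability p = second-slot frequency of `second` divided by the pair
#' total; positive scores mark attraction (observed above the chance
#' expectation n*p), negative scores repulsion, and an observed count equal
#' to the expectation scores exactly 0 (independent). Because the score is
#' a log-transformed exact binomial probability it needs no large-sample
#' assumptions, which suits the small, skewed corpora typical of animal
#' vocal data.
#'
#' Raw scores carry no multiplicity correction — the per-pair band mirrors
#' the conventional pbin reading. A Holm-adjusted band over all pairs tested
#' in the same call is reported alongside in `band_holm` for users who want
#' family-wise control.
#'
#' @param data A `bigram_table` or anything [tabulate_bigrams()] accepts.
#' @param all If `FALSE` (default) keep only pairs observed at least once;
#'   if `TRUE`, every ordered pair whose first call occurs in the first slot
#'   is scored (unobserved pairs come out as repulsion or independent).
#' @param ... Passed to [tabulate_bigrams()] for data-frame input.
#' @return A tibble of class `colloc_mdca`, one row per ordered pair, with
#'   columns `first`, `second`, `observed` (k), `trials` (n),
#'   `success_prob` (p), `expected` (n*p), `score`, `direction`, `band` and
#'   `band_holm`, sorted by descending score then label.
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' mdca(se)
#' @export
mdca <- function(data, all = FALSE, ...) {
  tab <- tabulate_bigrams(data, ...)
  if (tab$n_pairs == 0) {
    return(new_mdca(tibble::tibble(first = character(), second = character(),
                                   observed = integer(), trials = integer(),
                                   success_prob = double(), expected = double(),
                                   score = double(), direction = character(),
                                   band = character(), band_holm = character())))
  }
  grid <- tidyr::expand_grid(first = tab$labels, second = tab$labels)
  grid <- grid[tab$f_first[grid$first] > 0, ]
  k <- as.integer(tab$counts[cbind(grid$first, grid$second)])
  n <- as.integer(tab$f_first[grid$first])
  p <- unname(tab$f_second[grid$second]) / tab$n_pairs
  core <- mdca_core(k, n, p)
  res <- tibble::tibble(first = grid$first, second = grid$second,
                        observed = k, trials = n, success_prob = p,
                        expected = core$expected, score = core$score,
                        direction = core$direction,
                        band = significance_band(core$score))
  # Holm over the whole family of pairs scored here, on the raw tail p.
  p_raw <- 10^(-abs(res$score))
  p_holm <- stats::p.adjust(p_raw, method = "holm")
  res$band_holm <- significance_band(-log10(pmax(p_holm, .Machine$double.xmin)))
  if (!all) res <- res[res$observed > 0, ]
  new_mdca(dplyr::arrange(res, dplyr::desc(.data$score),
                          .data$first, .data$second))
}

new_mdca <- function(x) {
  class(x) <- c("colloc_mdca", class(tibble::tibble()))
  x
}

#' Score a single ordered call pair (MDCA)
#'
#' @inheritParams mdca
#' @param first,second Call labels of the ordered pair.
#' @return A one-row tibble in the format of [mdca()] (without the Holm
#'   column, which is only defined over a family of tests).
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' mdca_score(se, "Huff", "Puff")
#' @export
mdca_score <- function(data, first, second, ...) {
  tab <- tabulate_bigrams(data, ...)
  for (lab in c(first, second)) {
    if (!lab %in% tab$labels) {
      rlang::abort(paste0("Call label not in the repertoire: ", lab),
                   class = "colloc_unknown_label")
    }
  }
  if (tab$f_first[first] == 0) {
    rlang::abort(paste0("`", first, "` never occupies the first slot; ",
                        "its binomial trial count is 0 and no MDCA score ",
                        "is defined."),
                 class = "colloc_no_trials")
  }
  k <- as.integer(tab$counts[first, second])
  n <- as.integer(tab$f_first[first])
  p <- unname(tab$f_second[second]) / tab$n_pairs
  if (p == 0 && k > 0) {
    rlang::abort("Internal inconsistency: observed pair with zero second-slot marginal.",
                 class = "colloc_internal")
  }
  core <- mdca_core(k, n, p)
  new_mdca(tibble::tibble(first = first, second = second, observed = k,
                          trials = n, success_prob = p,
                          expected = core$expected, score = core$score,
                          direction = core$direction,
                          band = significance_band(core$score)))
}

#' Order asymmetry (linearisation) of a call pair
#'
#' MDCA scores ordered pairs, so comparing A-B with B-A asks whether a
#' combination is sensitive to call order. A pair is classified `"ordered"`
#' when exactly one direction shows a significant attraction (|score| > 1.3,
#' the p < 0.05 band), `"bidirectional"` when both do, and `"none"` when
#' neither does. A direction whose first call never occupies the first slot
#' has no defined binomial and counts as not significant.
#'
#' @inheritParams mdca
#' @param a,b Distinct call labels.
#' @return A one-row tibble: `call_a`, `call_b`, `score_ab`, `band_ab`,
#'   `score_ba`, `band_ba` (NA when undefined) and `ordering`.
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' order_asymmetry(se, "Peep", "Howl")
#' @export
order_asymmetry <- function(data, a, b, ...) {
  if (identical(a, b)) {
    rlang::abort("order_asymmetry() needs two distinct call labels.",
                 class = "colloc_bad_input")
  }
  tab <- tabulate_bigrams(data, ...)
  one_way <- function(x, y) {
    if (!x %in% tab$labels || !y %in% tab$labels || tab$f_first[x] == 0) {
      return(list(score = NA_real_, band = NA_character_, sig = FALSE))
    }
    r <- mdca_score(tab, x, y)
    list(score = r$score, band = r$band,
         sig = r$direction == "attraction" && abs(r$score) > 1.3)
  }
  ab <- one_way(a, b)
  ba <- one_way(b, a)
  ordering <- if (ab$sig && ba$sig) "bidirectional"
              else if (ab$sig || ba$sig) "ordered"
              else "none"
  tibble::tibble(call_a = a, call_b = b,
                 score_ab = ab$score, band_ab = ab$band,
                 score_ba = ba$score, band_ba = ba$band,
                 ordering = ordering)
}

#' @export
glance.colloc_mdca <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x),
                 n_attraction = sum(x$direction == "attraction"),
                 n_significant = sum(x$band != "NS"),
                 max_score = if (nrow(x)) max(x$score) else NA_real_)
}
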