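# MICA expectation: product of the two call-token frequencies over the
# call-token total. The denominator is the number of call tokens (2x the
# number of pairs for a pure bigram corpus), which is what makes the score
# exactly invariant to scaling every count by a constant.
mica_expected <- function(tab, a, b) {
  unname(tab$f_token[a]) * unname(tab$f_token[b]) / tab$n_calls
}

mica_one <- function(tab, a, b) {
  observed <- if (a == b) tab$counts[a, a] else tab$counts[a, b] + tab$counts[b, a]
  expected <- mica_expected(tab, a, b)
  if (observed == 0) {
    score <- NA_real_
    direction <- "not-observed"
    band <- NA_character_
  } else {
    score <- log2(observed / expected)
    direction <- if (abs(score) < 1e-12) "independent"
                 else if (score > 0) "attraction" else "repulsion"
    if (direction == "independent") score <- 0
    band <- significance_band(score)
  }
  pair <- sort(c(a, b))
  tibble::tibble(call_a = pair[1], call_b = pair[2],
                 observed = as.integer(observed), expected = expected,
                 score = score, direction = direction, band = band)
}

#' Mutual Information Collocation Analysis
#'
#' Scores each unordered call pair by the binary-log ratio of its observed
#' frequency to the frequency expected if call tokens were distributed
#' independently: score = log2(observed / expected) with
#' expected = f_token(a) * f_token(b) / n_calls, where f_token is a call's
#' total token frequency (first plus second slot) and n_calls the call-token
#' total. A score of 0 means the two calls co-occur exactly at chance;
#' positive scores mark attraction, negative repulsion. Counts are collapsed
#' over order (A-B and B-A are the same combination), so the score is
#' symmetric; it is also exactly invariant to multiplying every count by a
#' constant, and within one corpus it ranks rarer exclusive pairs above
#' commoner ones — the classic mutual-information emphasis on low-frequency
#' collocations.
#'
#' Band labels reuse the pbin convention of [significance_band()] applied to
#' the score magnitude; for MI values this is a labelling convention, not a
#' calibrated test.
#'
#' @param data A `bigram_table` or anything [tabulate_bigrams()] accepts.
#' @param all If `FALSE` (default) keep only pairs observed at least once;
#'   if `TRUE`, list every unordered pair of calls with positive token
#'   frequency (unobserved pairs get score `NA` and direction
#'   `"not-observed"`; no pseudo-count smoothing is applied).
#' @param ... Passed to [tabulate_bigrams()] for data-frame input.
#' @return A tibble of class `colloc_mica`, one row per unordered pair
#'   (written alphabetically), with columns `call_a`, `call_b`, `observed`,
#'   `expected`, `score`, `direction`, `band`, sorted by descending score
#'   then label.
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' mica(se)
#' @export
mica <- function(data, all = FALSE, ...) {
  tab <- tabulate_bigrams(data, ...)
  empty <- tibble::tibble(call_a = character(), call_b = character(),
                          observed = integer(), expected = double(),
                          score = double(), direction = character(),
                          band = character())
  if (tab$n_pairs == 0) return(new_mica(empty))
  labs <- tab$labels[tab$f_token[tab$labels] > 0]
  pairs <- tidyr::expand_grid(call_a = labs, call_b = labs)
  pairs <- pairs[pairs$call_a <= pairs$call_b, ]
  res <- purrr::pmap(pairs, function(call_a, call_b) mica_one(tab, call_a, call_b)) |>
    purrr::list_rbind()
  if (!all) res <- res[res$observed > 0, ]
  new_mica(dplyr::arrange(res, dplyr::desc(.data$score),
                          .data$call_a, .data$call_b))
}

new_mica <- function(x) {
  class(x) <- c("colloc_mica", class(tibble::tibble()))
  x
}

#' Score a single unordered call pair (MICA)
#'
#' @inheritParams mica
#' @param a,b Call labels (order irrelevant; `a == b` scores the self-pair).
#' @return A one-row tibble in the format of [mica()].
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' mica_score(se, "Peep", "Howl")
#' @export
mica_score <- function(data, a, b, ...) {
  tab <- tabulate_bigrams(data, ...)
  for (lab in unique(c(a, b))) {
    if (!lab %in% tab$labels || tab$f_token[lab] == 0) {
      rlang::abort(paste0("Call `", lab, "` has zero token frequency in this ",
                          "corpus; its MICA expectation is undefined."),
                   class = "colloc_unknown_label")
    }
  }
  new_mica(mica_one(tab, a, b))
}

#' @export
glance.colloc_mica <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_attraction = sum(x$direction == "attraction", na.rm = TRUE),
                 max_score = if (any(is.finite(x$score))) max(x$score, na.rm = TRUE)
                             else NA_real_)
}
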