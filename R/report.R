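#' Combined collocation report
#'
#' The two statistics have complementary strengths — the binomial score
#' (MDCA) grows with sample size, resolves call order, and weights common
#' combinations; the mutual-information score (MICA) is sample-size
#' invariant and flags rare exclusive pairs — so the recommended workflow is
#' to run both and compare. This report bundles, for one corpus: the full
#' MDCA table, the MICA table, an order-asymmetry classification for every
#' observed unordered pair, and a joint ranking of candidate combinations.
#'
#' The joint ranking keeps unordered pairs observed at least once, takes
#' each pair's best directed MDCA attraction score and its MICA score, ranks
#' the pairs under each statistic separately, and orders them by the sum of
#' the two ranks (ties broken by best single score, then alphabetically), so
#' the top rows are the pairs with the strongest collocational association
#' over both analyses. Output ordering is deterministic.
#'
#' @param data A `bigram_table` or anything [tabulate_bigrams()] accepts.
#' @param ... Passed to [tabulate_bigrams()] for data-frame input.
#' @return A list of class `colloc_report` with elements `mdca`, `mica`,
#'   `ordering`, `joint` and `table`.
#' @examples
#' colloc_report(artificial_corpus("SE"))
#' @export
colloc_report <- function(data, ...) {
  tab <- tabulate_bigrams(data, ...)
  res_mdca <- mdca(tab)
  res_mica <- mica(tab)
  ordering <- if (nrow(res_mica)) {
    purrr::pmap(res_mica[res_mica$call_a != res_mica$call_b,
                         c("call_a", "call_b")],
                function(call_a, call_b) order_asymmetry(tab, call_a, call_b)) |>
      purrr::list_rbind()
  } else {
    tibble::tibble(call_a = character(), call_b = character(),
                   score_ab = double(), band_ab = character(),
                   score_ba = double(), band_ba = character(),
                   ordering = character())
  }
  joint <- joint_ranking(res_mdca, res_mica, ordering)
  structure(list(table = tab, mdca = res_mdca, mica = res_mica,
                 ordering = ordering, joint = joint),
            class = "colloc_report")
}

joint_ranking <- function(res_mdca, res_mica, ordering) {
  empty <- tibble::tibble(call_a = character(), call_b = character(),
                          mdca_score = double(), mica_score = double(),
                          ordering = character(), joint_rank = integer())
  if (nrow(res_mica) == 0) return(empty)
  best_mdca <- res_mdca |>
    dplyr::mutate(call_a = pmin(.data$first, .data$second),
                  call_b = pmax(.data$first, .data$second)) |>
    dplyr::group_by(.data$call_a, .data$call_b) |>
    dplyr::summarise(mdca_score = max(.data$score), .groups = "drop")
  joint <- res_mica |>
    dplyr::select("call_a", "call_b", mica_score = "score") |>
    dplyr::left_join(best_mdca, by = c("call_a", "call_b")) |>
    dplyr::left_join(ordering[, c("call_a", "call_b", "ordering")],
                     by = c("call_a", "call_b")) |>
    dplyr::mutate(
      ordering = dplyr::coalesce(.data$ordering, "none"),
      rank_sum = rank(-.data$mdca_score, ties.method = "min", na.last = "keep") +
        rank(-.data$mica_score, ties.method = "min", na.last = "keep"),
      best = pmax(.data$mdca_score, .data$mica_score, na.rm = TRUE)) |>
    dplyr::arrange(.data$rank_sum, dplyr::desc(.data$best),
                   .data$call_a, .data$call_b) |>
    dplyr::mutate(joint_rank = dplyr::row_number()) |>
    dplyr::select("call_a", "call_b", "mdca_score", "mica_score",
                  "ordering", "joint_rank")
  joint
}

#' @export
print.colloc_report <- function(x, round = 2, ...) {
  cat(sprintf("Collocation report: %d call types, %d bigram tokens, %d call tokens\n\n",
              length(x$table$labels), x$table$n_pairs, x$table$n_calls))
  if (nrow(x$joint) == 0) {
    cat("Empty corpus: nothing to report.\n")
    return(invisible(x))
  }
  cat("Joint ranking (best candidates over both analyses):\n")
  j <- x$joint
  for (i in seq_len(nrow(j))) {
    cat(sprintf("  %d. %s-%s  MDCA %s  MICA %s  order: %s\n",
                j$joint_rank[i], j$call_a[i], j$call_b[i],
                format(round(j$mdca_score[i], round)),
                format(round(j$mica_score[i], round)), j$ordering[i]))
  }
  cat(sprintf("\nMDCA: %d ordered pair(s) scored, %d in a significance band.\n",
              nrow(x$mdca), sum(x$mdca$band != "NS")))
  cat(sprintf("MICA: %d unordered pair(s) scored.\n", nrow(x$mica)))
  invisible(x)
}

#' @export
tidy.colloc_report <- function(x, ...) x$joint

#' @export
glance.colloc_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$table$n_pairs,
                 n_calls = x$table$n_calls,
                 n_candidates = nrow(x$joint),
                 n_mdca_significant = sum(x$mdca$band != "NS"),
                 n_ordered = sum(x$joint$ordering == "ordered"))
}
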