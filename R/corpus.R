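#' Declare a call-type repertoire
#'
#' A repertoire is the inventory of distinct call-type labels available to a
#' data set (e.g. the vocal repertoire of a species). Labels are trimmed of
#' surrounding whitespace and matched case-sensitively everywhere in the
#' package.
#'
#' @param labels Character vector of distinct call-type labels.
#' @return A character vector of class `colloc_repertoire`.
#' @examples
#' repertoire(c("Huff", "Puff", "Peep", "Howl"))
#' @export
repertoire <- function(labels) {
  if (length(labels) == 0) {
    rlang::abort("A repertoire needs at least one call-type label.",
                 class = "colloc_bad_repertoire")
  }
  labels <- trimws(as.character(labels))
  if (any(is.na(labels)) || any(labels == "")) {
    rlang::abort("Repertoire labels must not be missing or whitespace-only.",
                 class = "colloc_bad_repertoire")
  }
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    rlang::abort(paste0("Duplicated repertoire label(s): ",
                        paste(dup, collapse = ", ")),
                 class = "colloc_bad_repertoire")
  }
  structure(labels, class = "colloc_repertoire")
}

#' The ten-call demonstration repertoire
#'
#' Ten hypothetical call types, broadly the size of a primate vocal
#' repertoire, used by the built-in artificial data sets: Huff, Puff, Peep,
#' Howl plus six further types ranging from tonal whistles to noisy barks.
#'
#' @return A `colloc_repertoire` of length 10.
#' @export
default_repertoire <- function() {
  repertoire(c("Huff", "Puff", "Peep", "Howl", "Whistle",
               "Twitter", "Bark", "Cough", "Chirp", "Grunt"))
}

#' Build a corpus of bigram tokens
#'
#' A corpus is a multiset of ordered two-call combinations ("bigram tokens"),
#' the unit every analysis in this package consumes. Input is a data frame
#' with columns `first` and `second` (one row per token) and optionally
#' `count` (rows are expanded, so downstream code always sees one row per
#' token).
#'
#' @param data Data frame with columns `first`, `second` and optionally
#'   `count` (non-negative integers; absent means 1 per row).
#' @param repertoire Optional [repertoire()]. When supplied, every label in
#'   `data` must belong to it; when `NULL`, the repertoire is the sorted set
#'   of labels observed.
#' @param provenance Optional free-text note recording where the corpus came
#'   from (kept as an attribute and shown by `print()`).
#' @return A tibble of class `colloc_corpus` with columns `first`, `second`,
#'   one row per bigram token, carrying `repertoire` and `provenance`
#'   attributes.
#' @examples
#' as_corpus(data.frame(first = c("Huff", "Peep"), second = c("Puff", "Howl"),
#'                      count = c(4, 5)))
#' @export
as_corpus <- function(data, repertoire = NULL, provenance = NULL) {
  data <- tibble::as_tibble(data)
  need <- c("first", "second")
  if (!all(need %in% names(data))) {
    rlang::abort("A pair-list corpus needs columns `first` and `second`.",
                 class = "colloc_bad_input")
  }
  data$first <- trimws(as.character(data$first))
  data$second <- trimws(as.character(data$second))
  if ("count" %in% names(data)) {
    cnt <- data$count
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
      rlang::abort("`count` must contain non-negative integers.",
                   class = "colloc_bad_input")
    }
    data <- data[rep(seq_len(nrow(data)), times = cnt), need]
  } else {
    data <- data[need]
  }
  labs <- unique(c(data$first, data$second))
  if (is.null(repertoire)) {
    rep_labels <- if (length(labs)) validate_repertoire(sort(labs)) else character()
  } else {
    rep_labels <- validate_repertoire(unclass(repertoire))
    bad <- setdiff(labs, rep_labels)
    if (length(bad)) {
      rlang::abort(paste0("Call label(s) not in the declared repertoire: ",
                          paste(bad, collapse = ", ")),
                   class = "colloc_unknown_label")
    }
  }
  structure(data,
            class = c("colloc_corpus", class(tibble::tibble())),
            repertoire = rep_labels,
            provenance = provenance %||% "unspecified")
}

#' @export
print.colloc_corpus <- function(x, ...) {
  cat(sprintf("<colloc_corpus> %d bigram tokens, %d call types (%s)\n",
              nrow(x), length(attr(x, "repertoire")), attr(x, "provenance")))
  NextMethod()
}

# Turn long-format sequence records into adjacent bigram tokens.
# window = "overlap": pairs (x1,x2),(x2,x3),...; "disjoint": (x1,x2),(x3,x4),...
sequences_to_pairs <- function(data, window) {
  data <- dplyr::arrange(tibble::as_tibble(data), .data$sequence_id, .data$position)
  split(data$call, data$sequence_id) |>
    purrr::map(function(calls) {
      m <- length(calls)
      if (m < 2) return(NULL)
      i <- if (window == "overlap") seq_len(m - 1) else seq(1L, m - 1L, by = 2L)
      tibble::tibble(first = calls[i], second = calls[i + 1L])
    }) |>
    purrr::list_rbind()
}

#' Cross-tabulate bigram frequencies
#'
#' Builds the square ordered-pair count matrix that both collocation
#' statistics are computed from, together with its marginals: `f_first`
#' (how often each call occupies the first slot), `f_second` (second slot),
#' and the call-token frequency `f_token = f_first + f_second`. For a pure
#' bigram corpus the call-token total `n_calls` is exactly twice the pair
#' total `n_pairs`.
#'
#' @param data A `colloc_corpus`, a pair-list data frame (columns `first`,
#'   `second`, optional `count`), or a sequence data frame (columns
#'   `sequence_id`, `position`, `call`) from which adjacent bigrams are
#'   extracted.
#' @param window For sequence input only: `"overlap"` (default) takes every
#'   adjacent pair, so a sequence A,B,C yields (A,B) and (B,C);
#'   `"disjoint"` takes non-overlapping pairs, yielding (A,B) only. Ignored
#'   for pair-list input, where the two modes coincide.
#' @param repertoire Optional [repertoire()] fixing the label set (and matrix
#'   order); labels outside it raise an error.
#' @return An object of class `bigram_table`: a list with the count matrix
#'   `counts` (first-slot label in rows, second-slot label in columns),
#'   named marginal vectors `f_first`, `f_second`, `f_token`, and totals
#'   `n_pairs`, `n_calls`.
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' tabulate_bigrams(se)
#' @export
tabulate_bigrams <- function(data, window = c("overlap", "disjoint"),
                             repertoire = NULL) {
  window <- match.arg(window)
  if (inherits(data, "bigram_table")) return(data)
  if (all(c("sequence_id", "position", "call") %in% names(data))) {
    seqs <- tibble::as_tibble(data)
    chk <- dplyr::summarise(
      dplyr::group_by(seqs, .data$sequence_id),
      ok = identical(sort(as.integer(.data$position)),
                     seq_len(dplyr::n())),
      .groups = "drop")
    if (!all(chk$ok)) {
      bad <- chk$sequence_id[!chk$ok]
      rlang::abort(paste0("Positions must be consecutive integers from 1 ",
                          "within each sequence; offending sequence(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "colloc_bad_input")
    }
    data <- sequences_to_pairs(seqs, window)
    if (is.null(data) || !all(c("first", "second") %in% names(data))) {
      data <- tibble::tibble(first = character(), second = character())
    }
  }
  corpus <- if (inherits(data, "colloc_corpus") && is.null(repertoire)) {
    data
  } else {
    as_corpus(data, repertoire = repertoire,
              provenance = attr(data, "provenance"))
  }
  labs <- as.character(attr(corpus, "repertoire"))
  counts <- matrix(0L, nrow = length(labs), ncol = length(labs),
                   dimnames = list(first = labs, second = labs))
  if (nrow(corpus) > 0) {
    tab <- table(factor(corpus$first, levels = labs),
                 factor(corpus$second, levels = labs))
    counts[] <- as.integer(tab)
  }
  f_first <- rowSums(counts)
  f_second <- colSums(counts)
  structure(
    list(counts = counts,
         labels = labs,
         f_first = f_first,
         f_second = f_second,
         f_token = f_first + f_second,
         n_pairs = sum(counts),
         n_calls = 2L * sum(counts),
         provenance = attr(corpus, "provenance")),
    class = "bigram_table")
}

#' @export
print.bigram_table <- function(x, ...) {
  cat(sprintf("<bigram_table> %d call types, %d bigram tokens, %d call tokens\n",
              length(x$labels), x$n_pairs, x$n_calls))
  print(x$counts)
  invisible(x)
}

#' Marginal call frequencies of a bigram table
#'
#' @param table A `bigram_table` (or anything [tabulate_bigrams()] accepts).
#' @return A tibble with one row per call type and columns `call`, `f_first`
#'   (first-slot frequency), `f_second` (second-slot frequency) and
#'   `f_token = f_first + f_second` (token frequency; an (A,A) self-pair
#'   contributes 2). Column sums of `f_first` and `f_second` equal `n_pairs`
#'   and `f_token` sums to `n_calls`.
#' @examples
#' se <- data.frame(first  = c("Huff", "Peep", "Howl"),
#'                  second = c("Puff", "Howl", "Peep"),
#'                  count  = c(4, 5, 7))
#' marginals(tabulate_bigrams(se))
#' @export
marginals <- function(table) {
  table <- tabulate_bigrams(table)
  tibble::tibble(call = table$labels,
                 f_first = unname(table$f_first),
                 f_second = unname(table$f_second),
                 f_token = unname(table$f_token))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bigram_table <- function(x, ...) {
  out <- tidyr::expand_grid(first = x$labels, second = x$labels)
  out$count <- as.integer(x$counts[cbind(out$first, out$second)])
  dplyr::arrange(out, .data$first, .data$second)
}

#' @export
glance.bigram_table <- function(x, ...) {
  tibble::tibble(n_types = length(x$labels),
                 n_pairs = x$n_pairs,
                 n_calls = x$n_calls,
                 n_observed_bigrams = sum(x$counts > 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# callable where an argument named `repertoire` shadows the constructor
validate_repertoire <- function(labels) repertoire(labels)
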