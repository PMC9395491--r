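delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read a pair-list corpus from delimited text
#'
#' The pair-list dialect is a comma- or tab-separated file (chosen by
#' extension: `.tsv`/`.tab`/`.txt` are tab, everything else comma) with a
#' header `first,second[,count]`. A missing `count` column means one token
#' per row; repeated rows aggregate by summation. A short parse report
#' (rows read, rows aggregated, labels discovered) is emitted as a message.
#'
#' @param path File path.
#' @param repertoire Optional [repertoire()] to validate labels against.
#' @return A `colloc_corpus`.
#' @export
read_pairs <- function(path, repertoire = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "colloc_io_error")
  }
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  if (!all(c("first", "second") %in% names(raw))) {
    rlang::abort(paste0("Pair-list file must have header first", delim_for(path),
                        "second[", delim_for(path), "count]: ", path),
                 class = "colloc_io_error")
  }
  if (nrow(raw) == 0) {
    rlang::warn(paste0("Empty pair-list file: ", path))
    return(as_corpus(tibble::tibble(first = character(), second = character()),
                     repertoire = repertoire, provenance = path))
  }
  bad <- which(is.na(raw$first) | is.na(raw$second) |
                 raw$first == "" | raw$second == "")
  if ("count" %in% names(raw)) {
    cnt <- suppressWarnings(as.numeric(raw$count))
    bad <- sort(union(bad, which(is.na(cnt) | cnt < 0 | cnt != round(cnt))))
  }
  if (length(bad)) {
    rlang::abort(paste0("Malformed row at line ", bad[1] + 1, " of ", path,
                        " (line 1 is the header)."),
                 class = "colloc_io_error")
  }
  pairs <- tibble::tibble(first = raw$first, second = raw$second,
                          count = if ("count" %in% names(raw))
                            as.integer(raw$count) else 1L)
  agg <- dplyr::summarise(dplyr::group_by(pairs, .data$first, .data$second),
                          count = sum(.data$count), .groups = "drop")
  corpus <- as_corpus(agg, repertoire = repertoire, provenance = path)
  rlang::inform(sprintf(
    "Read %d row(s) from %s: %d distinct bigram type(s), %d token(s), %d label(s).",
    nrow(raw), basename(path), nrow(agg), nrow(corpus),
    length(attr(corpus, "repertoire"))))
  corpus
}

#' Read call sequences from delimited text
#'
#' The sequence dialect is long-format delimited text with header
#' `sequence_id,position,call`; positions must be consecutive integers per
#' sequence starting at 1. The result feeds [tabulate_bigrams()], which
#' extracts adjacent bigrams per its `window` argument.
#'
#' @inheritParams read_pairs
#' @return A tibble with columns `sequence_id`, `position` (integer),
#'   `call`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "colloc_io_error")
  }
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  need <- c("sequence_id", "position", "call")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("Sequence file must have header sequence_id,position,call: ",
                        path), class = "colloc_io_error")
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- which(is.na(raw$sequence_id) | is.na(pos) | is.na(raw$call) |
                 raw$call == "")
  if (length(bad)) {
    rlang::abort(paste0("Malformed row at line ", bad[1] + 1, " of ", path,
                        " (line 1 is the header)."),
                 class = "colloc_io_error")
  }
  out <- tibble::tibble(sequence_id = raw$sequence_id, position = pos,
                        call = trimws(raw$call))
  # consecutive-position validation happens again in tabulate_bigrams();
  # doing it here names the file in the error
  chk <- dplyr::summarise(dplyr::group_by(out, .data$sequence_id),
                          ok = identical(sort(.data$position), seq_len(dplyr::n())),
                          .groups = "drop")
  if (!all(chk$ok)) {
    rlang::abort(paste0("Non-consecutive positions in sequence(s) ",
                        paste(utils::head(chk$sequence_id[!chk$ok], 5),
                              collapse = ", "), " of ", path),
                 class = "colloc_io_error")
  }
  out
}

#' Write a corpus as an aggregated pair list
#'
#' @param corpus A `colloc_corpus` or pair-list data frame.
#' @param path Output path; extension picks the delimiter as in
#'   [read_pairs()].
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- as_corpus(corpus, repertoire = attr(corpus, "repertoire"))
  agg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(corpus),
                                          .data$first, .data$second),
                          count = dplyr::n(), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$first, .data$second)
  readr::write_delim(agg, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Write a result table as delimited text
#'
#' Works for [mdca()], [mica()] and [marginals()] outputs (any data frame).
#'
#' @param x A data frame of results.
#' @param path Output path; extension picks the delimiter.
#' @param round Optional number of decimal places for numeric columns
#'   (e.g. `round = 1` mirrors conventional 1-dp score tables); `NULL`
#'   writes full precision.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, round = NULL) {
  x <- tibble::as_tibble(x)
  if (!is.null(round)) {
    x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double),
                                        ~ base::round(.x, round)))
  }
  readr::write_delim(x, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}
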