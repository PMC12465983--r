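# Corpus data frames: one row per study, columns ma_id, study_id,
# e1, n1, e0, n0 (arm 1 = treatment, arm 0 = control).

corpus_cols <- c("ma_id", "study_id", "e1", "n1", "e0", "n0")

#' Validate a corpus of two-arm binary-outcome studies
#'
#' Checks the long-format schema used throughout the package: one row per
#' study with columns `ma_id`, `study_id`, `e1`, `n1`, `e0`, `n0`, where
#' arm 1 is the treatment arm and arm 0 the control arm. Counts must be
#' whole numbers with `0 <= e <= n` and `n > 0` in both arms;
#' `(ma_id, study_id)` pairs must be unique and nothing may be missing.
#'
#' @param data A data frame in the corpus schema.
#' @return `data` as a tibble, invisibly validated (errors describe the
#'   offending rows by row number).
#' @examples
#' check_corpus(tibble::tibble(
#'   ma_id = "m1", study_id = c("s1", "s2"),
#'   e1 = c(3, 5), n1 = c(10, 20), e0 = c(2, 9), n0 = c(10, 20)
#' ))
#' @export
check_corpus <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "metafrag_bad_data")
  }
  missing_cols <- setdiff(corpus_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "metafrag_bad_data")
  }
  data <- tibble::as_tibble(data)
  cnt <- data[c("e1", "n1", "e0", "n0")]
  bad_na <- which(!stats::complete.cases(data[corpus_cols]))
  if (length(bad_na) > 0) {
    abort(paste0("Missing values in rows: ",
                 paste(head(bad_na, 5), collapse = ", ")),
          class = "metafrag_bad_data")
  }
  nonint <- which(vapply(seq_len(nrow(cnt)), function(i) {
    any(unlist(cnt[i, ]) %% 1 != 0)
  }, logical(1)))
  if (length(nonint) > 0) {
    abort(paste0("Counts must be whole numbers; offending rows: ",
                 paste(head(nonint, 5), collapse = ", ")),
          class = "metafrag_bad_data")
  }
  bad <- which(cnt$n1 <= 0 | cnt$n0 <= 0 |
                 cnt$e1 < 0 | cnt$e0 < 0 |
                 cnt$e1 > cnt$n1 | cnt$e0 > cnt$n0)
  if (length(bad) > 0) {
    abort(paste0("Count invariants violated (need 0 <= e <= n, n > 0) ",
                 "in rows: ", paste(head(bad, 5), collapse = ", ")),
          class = "metafrag_bad_data")
  }
  key <- paste(data$ma_id, data$study_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("Duplicate (ma_id, study_id) pairs in rows: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "metafrag_bad_data")
  }
  for (col in c("e1", "n1", "e0", "n0")) data[[col]] <- as.integer(data[[col]])
  data
}

# validate that `data` holds exactly one meta-analysis with >= 1 study;
# tolerates absent ma_id/study_id by filling defaults
one_ma <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty data frame of studies.",
          class = "metafrag_bad_data")
  }
  data <- tibble::as_tibble(data)
  if (!"ma_id" %in% names(data)) data$ma_id <- "ma"
  if (!"study_id" %in% names(data)) {
    data$study_id <- paste0("study_", seq_len(nrow(data)))
  }
  if (length(unique(data$ma_id)) > 1) {
    abort("`data` contains more than one ma_id; supply a single meta-analysis.",
          class = "metafrag_bad_data")
  }
  check_corpus(data[corpus_cols])
}

#' Read a corpus from a delimited text file
#'
#' Reads the long-format CSV schema (`ma_id, study_id, e1, n1, e0, n0`,
#' header required, UTF-8) and validates every row. Any malformed row
#' rejects the whole file with an error naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble, one row per study.
#' @seealso [write_corpus()], [check_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "metafrag_bad_data")
  }
  data <- readr::read_csv(path, col_types = readr::cols(
    ma_id = readr::col_character(),
    study_id = readr::col_character(),
    e1 = readr::col_double(), n1 = readr::col_double(),
    e0 = readr::col_double(), n0 = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(data)
  if (nrow(prob) > 0) {
    abort(paste0("Malformed input at line(s): ",
                 paste(head(unique(prob$row), 5) + 1L, collapse = ", ")),
          class = "metafrag_bad_data")
  }
  check_corpus(data)
}

#' Write a corpus to a delimited text file
#'
#' @param data A corpus data frame (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(data, path) {
  data <- check_corpus(data)
  readr::write_csv(data[corpus_cols], path, progress = FALSE)
  invisible(path)
}

# split a corpus into a named list of per-MA tibbles, preserving order;
# fills default identifiers when absent (single-MA convenience)
split_corpus <- function(data) {
  if (is.data.frame(data)) {
    data <- tibble::as_tibble(data)
    if (!"ma_id" %in% names(data)) data$ma_id <- "ma"
    if (!"study_id" %in% names(data)) {
      data$study_id <- paste0(data$ma_id, "_s", stats::ave(
        seq_len(nrow(data)), data$ma_id, FUN = seq_along))
    }
  }
  data <- check_corpus(data)
  split(data, factor(data$ma_id, levels = unique(data$ma_id)))
}
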