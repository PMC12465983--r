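# JSON serialisation of results.  All numbers are written at 17
# significant digits so repeated runs produce byte-identical files.

json_digits <- I(17)

#' Write analysis results as JSON
#'
#' Serialises a `meta_pool`, `fragility`, `improvement` or
#' `corpus_summary` object (or a plain list/tibble of results) to JSON
#' with stable 17-significant-digit number formatting.
#'
#' @param x The object to serialise.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_results_json <- function(x, path = NULL) {
  payload <- results_payload(x)
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = json_digits,
                                         pretty = TRUE, na = "null")))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = json_digits, pretty = TRUE, na = "null")
  invisible(path)
}

results_payload <- function(x) {
  if (inherits(x, "meta_pool")) {
    g <- glance(x)
    c(as.list(g), list(verdict = assess_significance(x)))
  } else if (inherits(x, "fragility")) {
    g <- as.list(glance(x))
    g$scenario <- if (!is.null(x$spec$scenario)) x$spec$scenario else NULL
    g$measure <- if (!is.null(x$spec$measure)) x$spec$measure else NULL
    g$plan <- x$plan
    g
  } else if (inherits(x, "improvement")) {
    g <- as.list(glance(x))
    g$study_fis <- x$study_fis
    g
  } else if (inherits(x, "corpus_summary")) {
    unclass(x)
  } else {
    x
  }
}
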