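#' Apply the continuity-correction policy to study counts
#'
#' Under the `"zero-cells"` policy, any study with at least one zero among
#' events and non-events in either arm gets 0.5 added to all four cells
#' (events and non-events in both arms), so corrected arm sizes become
#' `n + 1`. Other studies are returned unchanged. The correction is
#' re-resolved on every fit, because event-status modifications can create
#' or remove zero cells.
#'
#' @param data A data frame with columns `e1`, `n1`, `e0`, `n0` (one row
#'   per study); extra columns are preserved.
#' @param correction `"zero-cells"` (default) or `"none"`.
#' @return A tibble with real-valued columns `a1` (events, arm 1), `b1`
#'   (non-events, arm 1), `a0`, `b0` (arm 0), `m1`, `m0` (corrected arm
#'   sizes) and a logical `corrected` flag, alongside the input columns.
#' @examples
#' apply_continuity_correction(
#'   tibble::tibble(e1 = c(0, 3), n1 = 10, e0 = 2, n0 = 10)
#' )
#' @export
apply_continuity_correction <- function(data,
                                        correction = c("zero-cells", "none")) {
  correction <- match.arg(correction)
  data <- tibble::as_tibble(data)
  zero <- data$e1 == 0 | data$e1 == data$n1 | data$e0 == 0 | data$e0 == data$n0
  docorr <- if (correction == "none") rep(FALSE, nrow(data)) else zero
  half <- 0.5 * docorr
  dplyr::mutate(data,
    a1 = .data$e1 + half, b1 = (.data$n1 - .data$e1) + half,
    a0 = .data$e0 + half, b0 = (.data$n0 - .data$e0) + half,
    m1 = .data$n1 + docorr, m0 = .data$n0 + docorr,
    corrected = docorr
  )
}

#' Study-level effect estimates on the analysis scale
#'
#' Converts each study's 2x2 table into a point estimate `yi` and standard
#' error `sei` on the analysis scale: log odds ratio with
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, log relative risk with
#' `sqrt(1/e1 - 1/n1 + 1/e0 - 1/n0)`, or risk difference with
#' `sqrt(p1 (1 - p1) / n1 + p0 (1 - p0) / n0)`, all over continuity-
#' corrected cells where the policy applies. Double-zero studies (no events
#' in either arm) are non-informative for relative measures under the
#' default policy and carry `NA` estimates with `informative = FALSE`.
#'
#' @inheritParams apply_continuity_correction
#' @param measure `"OR"`, `"RR"` or `"RD"`.
#' @param double_zero `"exclude"` (default) or `"correct"`; see
#'   [scenario_spec()].
#' @return The input tibble with columns `yi`, `sei`, `corrected`,
#'   `informative` appended.
#' @examples
#' study_effects(
#'   tibble::tibble(e1 = 10, n1 = 100, e0 = 5, n0 = 100),
#'   measure = "OR"
#' )
#' @export
study_effects <- function(data, measure = c("OR", "RR", "RD"),
                          correction = c("zero-cells", "none"),
                          double_zero = c("exclude", "correct")) {
  measure <- match.arg(measure)
  correction <- match.arg(correction)
  double_zero <- match.arg(double_zero)
  data <- tibble::as_tibble(data)
  eff <- effects_core(matrix(data$e1, 1), matrix(data$n1, 1),
                      matrix(data$e0, 1), matrix(data$n0, 1),
                      measure, correction, double_zero)
  out <- dplyr::mutate(data,
    yi = as.vector(eff$y),
    sei = sqrt(as.vector(eff$s2)),
    corrected = as.vector(eff$corrected),
    informative = as.vector(eff$informative)
  )
  bad <- out$informative & (!is.finite(out$yi) | !is.finite(out$sei) |
                              out$sei <= 0)
  if (any(bad)) {
    abort(paste0("Degenerate study effect (non-finite standard error) in ",
                 "row(s): ", paste(which(bad), collapse = ", ")),
          class = "metafrag_degenerate_study")
  }
  out
}
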