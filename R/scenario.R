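#' Analysis scenario specification
#'
#' A scenario fixes every modelling choice needed to pool a meta-analysis:
#' the pooling model, the between-study variance estimator, the confidence
#' interval method, the effect measure, and the significance level. The five
#' named configurations are the fixed-effect model (`"FE"`) and four
#' random-effects variants: `"S1"` (REML with HKSJ), `"S2"` (REML, normal
#' intervals), `"S3"` (DL with HKSJ) and `"S4"` (DL, normal intervals).
#'
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"S4"`, `"FE"`.
#' @param measure Effect measure: `"OR"`, `"RR"` or `"RD"`. The odds ratio
#'   and relative risk are analysed on the log scale; the risk difference on
#'   the identity scale. The null effect is 0 on the analysis scale in all
#'   three cases.
#' @param alpha Two-sided significance level in (0, 1). Significance of a
#'   pooled result means its `100 * (1 - alpha)`% interval excludes 0 on the
#'   analysis scale.
#' @param correction Continuity correction policy: `"zero-cells"` (default)
#'   adds 0.5 to all four cells of any study with at least one zero among
#'   events and non-events in either arm; `"none"` disables correction.
#' @param double_zero Handling of studies with no events in either arm under
#'   relative measures (OR/RR): `"exclude"` (default) drops them as
#'   non-informative; `"correct"` retains them with continuity correction.
#'   Double-zero studies are always retained (corrected) for RD.
#' @param reml_tol,reml_maxit Convergence tolerance on successive tau-squared
#'   iterates and iteration cap for the REML fixed-point algorithm.
#'
#' @return An object of class `scenario_spec`: a list with elements
#'   `scenario`, `model` (`"FE"`/`"RE"`), `tau2_method` (`"DL"`/`"REML"`/
#'   `"none"`), `ci_method` (`"normal"`/`"HKSJ"`), `measure`, `alpha`,
#'   `correction`, `double_zero`, `reml_tol`, `reml_maxit`.
#' @examples
#' scenario_spec("S1", measure = "OR")
#' scenario_spec("FE", measure = "RD", alpha = 0.05)
#' @export
scenario_spec <- function(scenario = c("S1", "S2", "S3", "S4", "FE"),
                          measure = c("OR", "RR", "RD"),
                          alpha = 0.05,
                          correction = c("zero-cells", "none"),
                          double_zero = c("exclude", "correct"),
                          reml_tol = 1e-8, reml_maxit = 100L) {
  scenario <- match.arg(scenario)
  measure <- match.arg(measure)
  correction <- match.arg(correction)
  double_zero <- match.arg(double_zero)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).",
          class = "metafrag_bad_config")
  }
  cfg <- switch(scenario,
    FE = list(model = "FE", tau2_method = "none", ci_method = "normal"),
    S1 = list(model = "RE", tau2_method = "REML", ci_method = "HKSJ"),
    S2 = list(model = "RE", tau2_method = "REML", ci_method = "normal"),
    S3 = list(model = "RE", tau2_method = "DL", ci_method = "HKSJ"),
    S4 = list(model = "RE", tau2_method = "DL", ci_method = "normal")
  )
  structure(
    list(scenario = scenario, model = cfg$model, tau2_method = cfg$tau2_method,
         ci_method = cfg$ci_method, measure = measure, alpha = alpha,
         correction = correction, double_zero = double_zero,
         reml_tol = reml_tol, reml_maxit = as.integer(reml_maxit)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$scenario, ": ", x$model,
      if (x$model == "RE") paste0(" (tau2 = ", x$tau2_method, ", CI = ", x$ci_method, ")"),
      ", measure = ", x$measure, ", alpha = ", format(x$alpha), "\n", sep = "")
  invisible(x)
}

# resolve a scenario argument that may be a string or a scenario_spec
as_scenario_spec <- function(scenario, measure = "OR", alpha = 0.05, ...) {
  if (inherits(scenario, "scenario_spec")) return(scenario)
  scenario_spec(scenario, measure = measure, alpha = alpha, ...)
}
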