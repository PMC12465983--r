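# User-facing pooling layer.  The low-level verbs operate on an effects
# data frame (columns yi, sei, optionally informative); meta_pool() goes
# straight from a counts data frame to a fitted object.

effects_to_mats <- function(effects) {
  if (!all(c("yi", "sei") %in% names(effects))) {
    abort("`effects` must have columns `yi` and `sei` (see study_effects()).",
          class = "metafrag_bad_data")
  }
  y <- effects$yi
  s2 <- effects$sei^2
  if ("informative" %in% names(effects)) {
    y[!effects$informative] <- NA_real_
    s2[!effects$informative] <- NA_real_
  }
  list(y = matrix(y, 1), s2 = matrix(s2, 1))
}

require_k2 <- function(y) {
  if (sum(!is.na(y)) < 2L) {
    abort("At least 2 informative studies are required for pooling.",
          class = "metafrag_too_few_studies")
  }
}

#' Fixed-effect (common-effect) pooling
#'
#' Inverse-variance weighted mean of the study effects, with normal-theory
#' interval: `theta = sum(w yi) / sum(w)` with `w = 1/sei^2` and
#' `se = sum(w)^(-1/2)`.
#'
#' @param effects A data frame with columns `yi`, `sei` and optionally
#'   `informative` (as produced by [study_effects()]).
#' @param alpha Two-sided significance level for the interval.
#' @return A one-row tibble: `estimate`, `se`, `ci_lo`, `ci_hi`, `p_value`,
#'   `tau2` (0 by definition), `q`, `df`, `i2`, `k`.
#' @examples
#' pool_fixed(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
#' @export
pool_fixed <- function(effects, alpha = 0.05) {
  m <- effects_to_mats(effects)
  require_k2(m$y)
  spec <- scenario_spec("FE", alpha = alpha)
  res <- pool_core(m$y, m$s2, spec)
  tibble::tibble(estimate = res$est, se = res$se, ci_lo = res$ci_lo,
                 ci_hi = res$ci_hi, p_value = res$p, tau2 = res$tau2,
                 q = res$Q, df = res$Q_df, i2 = res$I2, k = res$k)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w (yi - theta_FE)^2)` with fixed-effect weights; the p-value is
#' from the chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @return A one-row tibble: `q`, `df`, `p_value`.
#' @export
q_statistic <- function(effects) {
  m <- effects_to_mats(effects)
  require_k2(m$y)
  res <- pool_core(m$y, m$s2, scenario_spec("FE"))
  tibble::tibble(q = res$Q, df = res$Q_df, p_value = res$Q_p)
}

#' Higgins' I-squared statistic
#'
#' The proportion of variation attributable to between-study heterogeneity:
#' `I2 = max(0, (Q - df) / Q)`, defined as 0 when `Q = 0`.
#'
#' @param q Heterogeneity statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return A value in `[0, 1]`.
#' @examples
#' i_squared(2, 1)
#' @export
i_squared <- function(q, df) {
  stopifnot(all(q >= 0), all(df >= 1))
  ifelse(q > 0, pmax(0, (q - df) / q), 0)
}

#' DerSimonian-Laird between-study variance estimator
#'
#' Non-iterative method-of-moments estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/sei^2`.
#'
#' @inheritParams pool_fixed
#' @return The estimated between-study variance (a single number >= 0).
#' @examples
#' tau2_dl(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
#' @export
tau2_dl <- function(effects) {
  m <- effects_to_mats(effects)
  require_k2(m$y)
  tau2_dl_core(m$y, m$s2)
}

#' REML between-study variance estimator
#'
#' Maximises the restricted log-likelihood of the random-effects model by
#' the standard fixed-point iteration, starting from the DL estimate and
#' truncating at 0. Non-convergence within `maxit` iterations is a reported
#' state (`converged = FALSE`, `tau2 = NA`), not an error.
#'
#' @inheritParams pool_fixed
#' @param tol Convergence tolerance on the change in successive tau-squared
#'   iterates.
#' @param maxit Maximum number of iterations.
#' @return A list with `tau2`, `converged` and `iterations`.
#' @examples
#' tau2_reml(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
#' @export
tau2_reml <- function(effects, tol = 1e-8, maxit = 100L) {
  m <- effects_to_mats(effects)
  require_k2(m$y)
  res <- tau2_reml_core(m$y, m$s2, tol = tol, maxit = maxit)
  list(tau2 = res$tau2, converged = res$converged,
       iterations = res$iterations)
}

#' Random-effects pooling with normal or HKSJ intervals
#'
#' Pools with weights `w* = 1/(sei^2 + tau2)`. The `"normal"` method uses
#' `se = sum(w*)^(-1/2)` and a z-interval; the `"HKSJ"` method uses the
#' weighted empirical variance
#' `sum(w* (yi - theta)^2) / ((k - 1) sum(w*))` with a t-interval on
#' `k - 1` degrees of freedom. A zero HKSJ variance (all informative `yi`
#' equal) is flagged `degenerate = TRUE` and judged by the interval as
#' computed, not patched.
#'
#' @inheritParams pool_fixed
#' @param tau2 Between-study variance (>= 0). If `NULL`, estimated with
#'   `tau2_method`.
#' @param tau2_method `"REML"` or `"DL"`, used when `tau2` is `NULL`.
#' @param ci_method `"normal"` or `"HKSJ"`.
#' @return A one-row tibble: `estimate`, `se`, `ci_lo`, `ci_hi`, `p_value`,
#'   `tau2`, `q`, `df`, `i2`, `k`, `converged`, `degenerate`.
#' @examples
#' eff <- tibble::tibble(yi = c(0, 2), sei = c(1, 1))
#' pool_random(eff, tau2 = 1, ci_method = "normal")
#' pool_random(eff, tau2 = 1, ci_method = "HKSJ")
#' @export
pool_random <- function(effects, tau2 = NULL,
                        tau2_method = c("REML", "DL"),
                        ci_method = c("HKSJ", "normal"),
                        alpha = 0.05) {
  tau2_method <- match.arg(tau2_method)
  ci_method <- match.arg(ci_method)
  m <- effects_to_mats(effects)
  require_k2(m$y)
  scn <- if (ci_method == "HKSJ") {
    if (tau2_method == "REML") "S1" else "S3"
  } else {
    if (tau2_method == "REML") "S2" else "S4"
  }
  spec <- scenario_spec(scn, alpha = alpha)
  if (!is.null(tau2)) {
    stopifnot(is.numeric(tau2), length(tau2) == 1L, tau2 >= 0)
    # fixed tau2: pool directly with the supplied value
    res <- pool_with_tau2(m$y, m$s2, tau2, spec)
  } else {
    res <- pool_core(m$y, m$s2, spec)
  }
  tibble::tibble(estimate = res$est, se = res$se, ci_lo = res$ci_lo,
                 ci_hi = res$ci_hi, p_value = res$p, tau2 = res$tau2,
                 q = res$Q, df = res$Q_df, i2 = res$I2, k = res$k,
                 converged = res$converged, degenerate = res$degenerate_var)
}

# pool at a fixed, user-supplied tau2 (no estimation step)
pool_with_tau2 <- function(y, s2, tau2, spec) {
  base <- pool_core(y, s2, scenario_spec("FE", alpha = spec$alpha))
  wp <- 1 / (s2 + tau2)
  swp <- rowSums(wp, na.rm = TRUE)
  est <- rowSums(wp * y, na.rm = TRUE) / swp
  df <- base$Q_df
  if (spec$ci_method == "HKSJ") {
    qh <- rowSums(wp * (y - est)^2, na.rm = TRUE) / pmax(df, 1L)
    vhk <- qh / swp
    se <- sqrt(vhk)
    crit <- qt(1 - spec$alpha / 2, pmax(df, 1L))
    p <- 2 * pt(-abs(est) / se, pmax(df, 1L))
    p[which(se == 0 & abs(est) > 0)] <- 0
    p[which(se == 0 & est == 0)] <- 1
    degenerate <- vhk <= 0
  } else {
    se <- sqrt(1 / swp)
    crit <- qnorm(1 - spec$alpha / 2)
    p <- 2 * pnorm(-abs(est) / se)
    degenerate <- rep(FALSE, length(est))
  }
  list(est = est, se = se, ci_lo = est - crit * se, ci_hi = est + crit * se,
       p = p, tau2 = rep(tau2, length(est)), Q = base$Q, Q_df = df,
       Q_p = base$Q_p, I2 = base$I2, k = base$k,
       converged = rep(TRUE, length(est)), degenerate_var = degenerate)
}

#' Fit one meta-analysis under an analysis scenario
#'
#' The main fitting entry point: takes a counts data frame for a single
#' meta-analysis (columns `e1`, `n1`, `e0`, `n0`, optionally `ma_id`,
#' `study_id`), resolves the continuity-correction and double-zero
#' policies, computes study effects, estimates between-study variance as
#' the scenario dictates, and pools.
#'
#' @param data A single meta-analysis in the corpus schema.
#' @param scenario A scenario name (`"FE"`, `"S1"`..`"S4"`) or a
#'   [scenario_spec()] object.
#' @param measure,alpha,... Passed to [scenario_spec()] when `scenario` is
#'   a name.
#' @return An object of class `meta_pool` with the pooled `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p_value`, `tau2`, `q`, `i2`, significance verdict,
#'   and the per-study effects tibble. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @examples
#' ma <- tibble::tibble(
#'   e1 = c(12, 11), n1 = c(20, 20), e0 = c(4, 5), n0 = c(20, 20)
#' )
#' fit <- meta_pool(ma, scenario = "FE", measure = "OR")
#' glance(fit)
#' @export
meta_pool <- function(data, scenario = "S1", measure = "OR", alpha = 0.05,
                      ...) {
  spec <- as_scenario_spec(scenario, measure = measure, alpha = alpha, ...)
  data <- one_ma(data)
  res <- fit_counts_core(matrix(data$e1, 1), matrix(data$n1, 1),
                         matrix(data$e0, 1), matrix(data$n0, 1), spec)
  if (!res$usable) {
    abort("At least 2 informative studies with finite standard errors are required.",
          class = "metafrag_too_few_studies")
  }
  effects <- study_effects(data, measure = spec$measure,
                           correction = spec$correction,
                           double_zero = spec$double_zero)
  structure(
    list(estimate = res$est, se = res$se, ci_lo = res$ci_lo,
         ci_hi = res$ci_hi, p_value = res$p, tau2 = res$tau2,
         tau = res$tau, q = res$Q, q_df = res$Q_df, q_p = res$Q_p,
         i2 = res$I2, k = res$k, converged = res$converged,
         degenerate = res$degenerate_var,
         significant = sig_core(res$ci_lo, res$ci_hi),
         total_n = sum(data$n1 + data$n0),
         total_events = sum(data$e1 + data$e0),
         effects = effects, data = data, spec = spec),
    class = "meta_pool"
  )
}

#' @export
print.meta_pool <- function(x, digits = 4, ...) {
  s <- x$spec
  scale_lab <- if (s$measure %in% c("OR", "RR")) {
    paste0("log ", s$measure)
  } else "RD"
  cat("Meta-analysis (", s$scenario, ": ", s$model,
      if (s$model == "RE") paste0(", tau2 = ", s$tau2_method,
                                  ", CI = ", s$ci_method),
      "), measure = ", s$measure, "\n", sep = "")
  if (!x$converged) {
    cat("REML did not converge; no pooled estimate.\n")
    return(invisible(x))
  }
  cat(sprintf("  %s = %.*f, 95%% CI [%.*f, %.*f], p = %.4g  (%s)\n",
              scale_lab, digits, x$estimate, digits, x$ci_lo, digits,
              x$ci_hi, x$p_value,
              if (x$significant) "significant" else "nonsignificant"))
  cat(sprintf("  k = %d, tau2 = %.*f, Q = %.*f (df = %d, p = %.4g), I2 = %.1f%%\n",
              x$k, digits, x$tau2, digits, x$q, x$q_df, x$q_p, 100 * x$i2))
  if (x$degenerate) cat("  note: degenerate (zero) HKSJ variance\n")
  invisible(x)
}

#' Significance verdict of a pooled result
#'
#' A result is significant when its confidence interval excludes the null
#' effect, which is 0 on the analysis scale for all three measures.
#'
#' @param object A `meta_pool` object, or anything with `ci_lo`/`ci_hi`
#'   elements or columns.
#' @return `"significant"` or `"nonsignificant"` (character vector).
#' @examples
#' assess_significance(list(ci_lo = 0.1, ci_hi = 0.5))
#' assess_significance(list(ci_lo = -0.1, ci_hi = 0.5))
#' @export
assess_significance <- function(object) {
  ci_lo <- if (is.list(object)) object$ci_lo else object["ci_lo"]
  ci_hi <- if (is.list(object)) object$ci_hi else object["ci_hi"]
  ifelse(sig_core(ci_lo, ci_hi), "significant", "nonsignificant")
}
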