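# broom-style methods for fitted objects

#' Tidy a pooled meta-analysis
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A tibble with one row per study: `study_id`, `yi`, `sei`,
#'   `weight` (normalised pooling weight), `corrected`, `informative`.
#' @export
tidy.meta_pool <- function(x, ...) {
  eff <- x$effects
  s2 <- eff$sei^2
  w <- ifelse(eff$informative, 1 / (s2 + x$tau2), 0)
  w <- w / sum(w, na.rm = TRUE)
  tibble::tibble(study_id = eff$study_id, yi = eff$yi, sei = eff$sei,
                 weight = w, corrected = eff$corrected,
                 informative = eff$informative)
}

#' Glance at a pooled meta-analysis
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A one-row tibble with the pooled `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `p_value`, `tau2`, `q`, `q_df`, `q_p`, `i2`, `k`,
#'   `converged`, `degenerate`, `significant`, and scenario identifiers.
#' @export
glance.meta_pool <- function(x, ...) {
  tibble::tibble(
    scenario = x$spec$scenario, measure = x$spec$measure,
    estimate = x$estimate, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    p_value = x$p_value, tau2 = x$tau2, q = x$q, q_df = x$q_df,
    q_p = x$q_p, i2 = x$i2, k = x$k, converged = x$converged,
    degenerate = x$degenerate, significant = x$significant
  )
}

#' Tidy a fragility result
#'
#' @param x A `fragility` object.
#' @param ... Unused.
#' @return The ordered modification plan: one row per applied flip with
#'   `step`, `study`, `study_id`, `arm`, `delta`, `p_after`.
#' @export
tidy.fragility <- function(x, ...) {
  x$plan
}

#' Glance at a fragility result
#'
#' @param x A `fragility` object.
#' @param ... Unused.
#' @return A one-row tibble: `fi`, `attainable`, `fq`, `direction`,
#'   `initial_verdict`, `p0`, `total_n`, `cap`, `method`.
#' @export
glance.fragility <- function(x, ...) {
  tibble::tibble(
    fi = x$fi, attainable = x$attainable, fq = x$fq,
    direction = x$direction, initial_verdict = x$initial_verdict,
    p0 = x$p0, total_n = x$total_n, cap = x$cap, method = x$method
  )
}

#' Tidy an improvement result
#'
#' @param x An `improvement` object.
#' @param ... Unused.
#' @return The per-study fragility tibble (`study_id`, `fi`,
#'   `attainable`).
#' @export
tidy.improvement <- function(x, ...) {
  x$study_fis
}

#' Glance at an improvement result
#'
#' @param x An `improvement` object.
#' @param ... Unused.
#' @return A one-row tibble: `proportion`, `category`, `ma_fi`,
#'   `n_studies`, `n_not_attainable`.
#' @export
glance.improvement <- function(x, ...) {
  tibble::tibble(
    proportion = x$proportion, category = as.character(x$category),
    ma_fi = x$ma_fi, n_studies = nrow(x$study_fis),
    n_not_attainable = x$n_not_attainable
  )
}
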