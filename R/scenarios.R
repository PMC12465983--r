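# Corpus-level scenario comparison: run the five analysis configurations
# across a corpus, compute paired differences, subgroup bins and summaries.

#' Run the five analysis scenarios across a corpus
#'
#' Fits every meta-analysis in `data` under each requested scenario and
#' effect measure, and (optionally) computes the fragility index of each
#' fit. REML non-convergence is recorded per row (`converged = FALSE`,
#' `NA` results) rather than raised.
#'
#' @param data A corpus data frame (see [read_corpus()]).
#' @param measures Character vector among `"OR"`, `"RR"`, `"RD"`.
#' @param scenarios Character vector among `"FE"`, `"S1"`..`"S4"`.
#' @param alpha Significance level.
#' @param fi Which rows get a fragility search: `"all"`, `"significant"`
#'   (only rows whose pooled interval excludes the null), or `"none"`.
#' @param cap Cap passed to [fragility_ma()] (`NULL` = its default).
#' @param beam Beam width passed to [fragility_ma()]; the corpus-scale
#'   default trades a little search thoroughness for speed.
#' @return A tibble with one row per meta-analysis x scenario x measure:
#'   identifiers, `k`, `total_n`, `total_events`, pooled results
#'   (`estimate`, `se`, `ci_lo`, `ci_hi`, `ci_len`, `p_value`, `tau2`, `q`,
#'   `i2`, `converged`, `degenerate`), `significant`, and when requested
#'   `fi`, `fi_attainable`, `fq`, `fi_direction`.
#' @examples
#' corpus <- generate_corpus(synthetic_config(n_mas = 3, seed = 1))
#' run_scenarios(corpus, measures = "OR", scenarios = c("FE", "S4"),
#'               fi = "none")
#' @export
run_scenarios <- function(data, measures = "OR",
                          scenarios = c("FE", "S1", "S2", "S3", "S4"),
                          alpha = 0.05, fi = c("all", "significant", "none"),
                          cap = NULL, beam = 10L) {
  fi <- match.arg(fi)
  mas <- split_corpus(data)
  grid <- tidyr::expand_grid(measure = measures, scenario = scenarios)
  purrr::map_dfr(mas, function(ma) {
    purrr::pmap_dfr(grid, function(measure, scenario) {
      run_one_scenario(ma, scenario, measure, alpha, fi, cap, beam)
    })
  })
}

run_one_scenario <- function(ma, scenario, measure, alpha, fi, cap, beam) {
  spec <- as_scenario_spec(scenario, measure = measure, alpha = alpha)
  base <- tibble::tibble(
    ma_id = ma$ma_id[1], measure = measure, scenario = scenario,
    k = nrow(ma), total_n = sum(ma$n1 + ma$n0),
    total_events = sum(ma$e1 + ma$e0),
    estimate = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    ci_len = NA_real_, p_value = NA_real_, tau2 = NA_real_, q = NA_real_,
    i2 = NA_real_, converged = FALSE, degenerate = FALSE,
    significant = NA, fi = NA_integer_, fi_attainable = NA,
    fq = NA_real_, fi_direction = NA_character_
  )
  res <- tryCatch(
    fit_counts_core(matrix(ma$e1, 1), matrix(ma$n1, 1),
                    matrix(ma$e0, 1), matrix(ma$n0, 1), spec),
    error = function(e) NULL
  )
  if (is.null(res) || !res$usable) return(base)
  base$converged <- res$converged
  if (!res$converged) return(base)
  base$estimate <- res$est; base$se <- res$se
  base$ci_lo <- res$ci_lo; base$ci_hi <- res$ci_hi
  base$ci_len <- res$ci_hi - res$ci_lo
  base$p_value <- res$p; base$tau2 <- res$tau2
  base$q <- res$Q; base$i2 <- res$I2
  base$degenerate <- res$degenerate_var
  base$significant <- sig_core(res$ci_lo, res$ci_hi)
  want_fi <- fi == "all" || (fi == "significant" && base$significant)
  if (want_fi) {
    fr <- tryCatch(
      fragility_ma(ma, scenario = scenario, measure = measure,
                   alpha = alpha, cap = cap, beam = beam),
      error = function(e) NULL
    )
    if (!is.null(fr)) {
      base$fi <- fr$fi
      base$fi_attainable <- fr$attainable
      base$fq <- fr$fq
      base$fi_direction <- fr$direction
    }
  }
  base
}

#' Paired scenario differences
#'
#' For each meta-analysis present in both scenarios, the difference in
#' fragility index (`scenario_a` minus `scenario_b`) and in confidence
#' interval length on the analysis scale. Rows with a non-attainable index
#' in either scenario are excluded and counted.
#'
#' @param results A [run_scenarios()] tibble.
#' @param scenario_a,scenario_b Scenario names to compare.
#' @param measure Effect measure to restrict to.
#' @return A tibble with `ma_id`, `fi_diff`, `ci_len_diff`; the number of
#'   excluded meta-analyses is in attribute `n_excluded`.
#' @export
paired_differences <- function(results, scenario_a, scenario_b,
                               measure = "OR") {
  a <- dplyr::filter(results, .data$scenario == scenario_a,
                     .data$measure == .env$measure)
  b <- dplyr::filter(results, .data$scenario == scenario_b,
                     .data$measure == .env$measure)
  j <- dplyr::inner_join(
    dplyr::select(a, "ma_id", fi_a = "fi", att_a = "fi_attainable",
                  len_a = "ci_len"),
    dplyr::select(b, "ma_id", fi_b = "fi", att_b = "fi_attainable",
                  len_b = "ci_len"),
    by = "ma_id"
  )
  ok <- !is.na(j$att_a) & !is.na(j$att_b) & j$att_a & j$att_b
  out <- tibble::tibble(
    ma_id = j$ma_id[ok],
    fi_diff = j$fi_a[ok] - j$fi_b[ok],
    ci_len_diff = j$len_a[ok] - j$len_b[ok]
  )
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Subgroup bins for total sample size and total events
#'
#' Half-open bins `[a, b)` with the conventions used throughout: sample
#' sizes `<50, 50-100, 100-200, 200-500, 500-1000, >=1000`; event counts
#' `<10, 10-50, 50-100, 100-500, 500-1000, >=1000`. A boundary value maps
#' to the bin it opens (50 to `"50-100"`, 1000 to `">=1000"`).
#'
#' @param total_n,total_events Positive totals (vectorised).
#' @return A factor of bin labels.
#' @examples
#' bin_sample_size(c(49, 50, 723, 1000))
#' bin_events(c(9, 10, 130, 1000))
#' @export
bin_sample_size <- function(total_n) {
  cut(total_n, breaks = c(0, 50, 100, 200, 500, 1000, Inf),
      labels = c("<50", "50-100", "100-200", "200-500", "500-1000",
                 ">=1000"),
      right = FALSE)
}

#' @rdname bin_sample_size
#' @export
bin_events <- function(total_events) {
  cut(total_events, breaks = c(0, 10, 50, 100, 500, 1000, Inf),
      labels = c("<10", "10-50", "50-100", "100-500", "500-1000",
                 ">=1000"),
      right = FALSE)
}

i2_band_defs <- tibble::tibble(
  band = c("not-important", "moderate", "substantial", "considerable"),
  lo = c(0, 0.3, 0.5, 0.75),
  hi = c(0.4, 0.6, 0.9, 1)
)

#' Overlapping heterogeneity bands for I-squared
#'
#' The Cochrane Handbook guideline ranges, which deliberately overlap:
#' not-important `[0, 0.4]`, moderate `[0.3, 0.6]`, substantial
#' `[0.5, 0.9]`, considerable `[0.75, 1]`. Every value belongs to at least
#' one band and possibly two.
#'
#' @param i2 I-squared value(s) in `[0, 1]`.
#' @return For a single value, a character vector of the containing bands;
#'   for a vector, a list of such vectors.
#' @examples
#' i2_bands(0.35)
#' i2_bands(0.8)
#' @export
i2_bands <- function(i2) {
  stopifnot(all(i2 >= 0 & i2 <= 1))
  one <- function(x) {
    i2_band_defs$band[x >= i2_band_defs$lo & x <= i2_band_defs$hi]
  }
  if (length(i2) == 1L) one(i2) else lapply(i2, one)
}

#' Non-overlapping I-squared strata
#'
#' A primary, mutually exclusive stratification used for improvement
#' analyses: `[0, 0.4)`, `[0.4, 0.6)`, `[0.6, 0.75)`, `[0.75, 1]`.
#' Configurable via `breaks`.
#'
#' @inheritParams i2_bands
#' @param breaks Increasing cut points spanning `[0, 1]`.
#' @return A factor of stratum labels.
#' @examples
#' i2_stratum(c(0, 0.4, 0.7, 0.9))
#' @export
i2_stratum <- function(i2, breaks = c(0, 0.4, 0.6, 0.75, 1)) {
  stopifnot(all(i2 >= 0 & i2 <= 1))
  cut(i2, breaks = breaks, right = FALSE, include.lowest = TRUE)
}

#' Effect-magnitude bands for OR and RR
#'
#' Values below 1 are inverted (`1/x`) before banding, so the band reflects
#' the magnitude of the effect regardless of direction. OR cutoffs
#' (consistent with Cohen's d): 1-1.68 small, 1.68-3.47 moderate,
#' 3.47-6.71 medium, >6.71 large. RR cutoffs: 1-1.22 small, 1.22-1.86
#' moderate, 1.86-3.00 medium, >=3.00 large. Bands are half-open `[a, b)`.
#' There is no analogous banding for the risk difference.
#'
#' @param or_value,rr_value Positive ratio(s) on the natural (not log)
#'   scale.
#' @return A factor with levels `small`, `moderate`, `medium`, `large`.
#' @examples
#' or_magnitude(c(0.4, 1, 1.68, 7))
#' rr_magnitude(c(1.1, 3))
#' @export
or_magnitude <- function(or_value) {
  stopifnot(all(or_value > 0))
  v <- ifelse(or_value < 1, 1 / or_value, or_value)
  cut(v, breaks = c(1, 1.68, 3.47, 6.71, Inf),
      labels = c("small", "moderate", "medium", "large"),
      right = FALSE, include.lowest = TRUE)
}

#' @rdname or_magnitude
#' @export
rr_magnitude <- function(rr_value) {
  stopifnot(all(rr_value > 0))
  v <- ifelse(rr_value < 1, 1 / rr_value, rr_value)
  cut(v, breaks = c(1, 1.22, 1.86, 3, Inf),
      labels = c("small", "moderate", "medium", "large"),
      right = FALSE, include.lowest = TRUE)
}

#' Corpus-level fragility summary
#'
#' Summarises a [run_scenarios()] result per scenario and measure,
#' restricted to the statistically significant meta-analyses (the subset
#' the fragility metrics describe). Reports counts, median/IQR of FI and
#' FQ, the proportions with FI = 1, FI <= 5, FI >= 22, FQ < 0.01 and
#' FQ < 0.05, and per-bin FI distributions by total sample size and total
#' events.
#'
#' @param results A [run_scenarios()] tibble with fragility columns.
#' @param improvement_results Optional tibble with columns `ma_id`,
#'   `measure`, `scenario`, `proportion` (improvement percentages); when
#'   given, improvement-category proportions by I-squared stratum are
#'   included.
#' @return An object of class `corpus_summary`: a list with tibbles
#'   `overall` (one row per scenario x measure), `by_bin` (FI medians and
#'   proportions per sample-size/event bin), and optionally
#'   `improvement_by_stratum`.
#' @export
summarize_corpus <- function(results, improvement_results = NULL) {
  if (nrow(results) == 0) {
    abort("Empty corpus results.", class = "metafrag_bad_data")
  }
  sig <- dplyr::filter(results, !is.na(.data$significant),
                       .data$significant)
  att <- dplyr::filter(sig, !is.na(.data$fi_attainable),
                       .data$fi_attainable)
  overall <- dplyr::summarise(
    dplyr::group_by(results, .data$scenario, .data$measure),
    n = dplyr::n(),
    n_converged = sum(.data$converged),
    n_significant = sum(.data$significant, na.rm = TRUE),
    .groups = "drop"
  )
  fi_sum <- dplyr::summarise(
    dplyr::group_by(att, .data$scenario, .data$measure),
    n_fi = dplyr::n(),
    fi_median = stats::median(.data$fi),
    fi_q1 = unname(quantile(.data$fi, 0.25, type = 2)),
    fi_q3 = unname(quantile(.data$fi, 0.75, type = 2)),
    fq_median = stats::median(.data$fq),
    fq_q1 = unname(quantile(.data$fq, 0.25, type = 2)),
    fq_q3 = unname(quantile(.data$fq, 0.75, type = 2)),
    prop_fi_1 = mean(.data$fi == 1),
    prop_fi_le5 = mean(.data$fi <= 5),
    prop_fi_ge22 = mean(.data$fi >= 22),
    prop_fq_lt_0.01 = mean(.data$fq < 0.01),
    prop_fq_lt_0.05 = mean(.data$fq < 0.05),
    .groups = "drop"
  )
  overall <- dplyr::left_join(overall, fi_sum,
                              by = c("scenario", "measure"))
  by_bin <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(att,
                    n_bin = bin_sample_size(.data$total_n),
                    e_bin = bin_events(.data$total_events)),
      .data$scenario, .data$measure, .data$n_bin, .data$e_bin),
    n = dplyr::n(),
    fi_median = stats::median(.data$fi),
    prop_fi_1 = mean(.data$fi == 1),
    prop_fi_le5 = mean(.data$fi <= 5),
    .groups = "drop"
  )
  out <- list(overall = overall, by_bin = by_bin)
  if (!is.null(improvement_results)) {
    imp <- dplyr::inner_join(
      improvement_results,
      dplyr::select(sig, "ma_id", "measure", "scenario", "i2"),
      by = c("ma_id", "measure", "scenario")
    )
    imp$stratum <- i2_stratum(imp$i2)
    imp$category <- categorize_improvement(imp$proportion)
    out$improvement_by_stratum <- dplyr::count(
      imp, .data$scenario, .data$measure, .data$stratum, .data$category
    ) |>
      dplyr::group_by(.data$scenario, .data$measure, .data$stratum) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  structure(out, class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("<corpus_summary> significant-subset fragility summary\n")
  print(x$overall, ...)
  invisible(x)
}
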