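# Fragility improvement of a meta-analysis over its included studies.

#' Improvement proportion
#'
#' Percentage of a meta-analysis' included studies whose fragility index is
#' strictly smaller (more fragile) than the meta-analysis' own index:
#' `100 / N * sum(FI_i < FI_MA)`. Studies whose index is not attainable
#' (`NA`) are treated as infinitely robust and never counted as smaller.
#'
#' @param ma_fi Fragility index of the meta-analysis (positive integer).
#' @param study_fis Numeric vector of per-study fragility indices; `NA`
#'   means not attainable.
#' @return A percentage in `[0, 100]`.
#' @examples
#' improvement_proportion(5, c(1, 2, 7))  # 66.67
#' @export
improvement_proportion <- function(ma_fi, study_fis) {
  if (length(study_fis) == 0) {
    abort("`study_fis` must contain at least one study.",
          class = "metafrag_bad_data")
  }
  stopifnot(is.numeric(ma_fi), length(ma_fi) == 1L, !is.na(ma_fi))
  smaller <- !is.na(study_fis) & study_fis < ma_fi
  100 * sum(smaller) / length(study_fis)
}

#' Categorise an improvement proportion
#'
#' Four levels: `"no"` improvement at exactly 0%, `"slight"` in (0, 50],
#' `"considerable"` in (50, 100), and `"complete"` at exactly 100%. The
#' boundary at 50% belongs to `"slight"`, mirroring the strict inequalities
#' that define the considerable range.
#'
#' @param proportion Percentage(s) in `[0, 100]`.
#' @return A factor with levels `no < slight < considerable < complete`.
#' @examples
#' categorize_improvement(c(0, 25, 50, 66.7, 100))
#' @export
categorize_improvement <- function(proportion) {
  if (any(is.na(proportion)) || any(proportion < 0 | proportion > 100)) {
    abort("`proportion` must be in [0, 100].", class = "metafrag_bad_data")
  }
  lv <- c("no", "slight", "considerable", "complete")
  out <- ifelse(proportion == 0, "no",
         ifelse(proportion <= 50, "slight",
         ifelse(proportion < 100, "considerable", "complete")))
  factor(out, levels = lv, ordered = TRUE)
}

#' Fragility improvement of a meta-analysis over its studies
#'
#' Computes the meta-analysis fragility index under the given scenario,
#' the per-study fragility indices under the per-study test, and the
#' improvement proportion and category.
#'
#' @inheritParams fragility_ma
#' @param study_method Per-study test passed to [fragility_study()].
#' @param study_cap Cap for the per-study searches (default: each study's
#'   sample size).
#' @return A list of class `improvement`: `proportion`, `category`,
#'   `ma_fi`, `study_fis` (tibble with `study_id`, `fi`, `attainable`),
#'   `n_not_attainable`.
#' @examples
#' ma <- tibble::tibble(
#'   e1 = c(12, 11), n1 = c(20, 20), e0 = c(4, 5), n0 = c(20, 20)
#' )
#' improvement(ma, scenario = "FE", measure = "OR")
#' @export
improvement <- function(data, scenario = "S1", measure = "OR", alpha = 0.05,
                        cap = NULL, study_method = "fisher",
                        study_cap = NULL, ...) {
  data <- one_ma(data)
  frag <- fragility_ma(data, scenario = scenario, measure = measure,
                       alpha = alpha, cap = cap, ...)
  if (!frag$attainable) {
    abort("The meta-analysis fragility index is not attainable within the cap; no improvement proportion.",
          class = "metafrag_not_attainable")
  }
  study_fis <- purrr::map(seq_len(nrow(data)), function(i) {
    fragility_study(e1 = data$e1[i], n1 = data$n1[i],
                    e0 = data$e0[i], n0 = data$n0[i],
                    method = study_method, alpha = alpha,
                    cap = if (is.null(study_cap)) NULL else study_cap)
  })
  fis <- purrr::map_int(study_fis, "fi")
  att <- purrr::map_lgl(study_fis, "attainable")
  prop <- improvement_proportion(frag$fi, fis)
  structure(
    list(proportion = prop,
         category = categorize_improvement(prop),
         ma_fi = frag$fi,
         study_fis = tibble::tibble(study_id = data$study_id, fi = fis,
                                    attainable = att),
         n_not_attainable = sum(!att),
         ma_fragility = frag),
    class = "improvement"
  )
}

#' @export
print.improvement <- function(x, ...) {
  cat(sprintf("<improvement> MA FI = %d vs %d studies: %.2f%% (%s improvement)\n",
              x$ma_fi, nrow(x$study_fis), x$proportion,
              as.character(x$category)))
  if (x$n_not_attainable > 0) {
    cat(sprintf("  %d study FI(s) not attainable (treated as robust)\n",
                x$n_not_attainable))
  }
  invisible(x)
}
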