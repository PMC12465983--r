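# Seeded generator of Cochrane-like corpora of binary-outcome
# meta-analyses.  The generative model mirrors the assumptions of the
# random-effects analysis: per study, a true log odds ratio drawn from
# N(theta, tau2), a control risk from a Beta distribution, arm sizes from
# a log-normal, and binomial event counts.  Default distribution
# parameters are calibrated once against published corpus marginals
# (median 4 studies per meta-analysis with IQR 3-8, median total sample
# size 723 with IQR 291-1934, median 130 total events).

#' Configuration for the synthetic corpus generator
#'
#' @param n_mas Number of meta-analyses in the corpus.
#' @param k_dist Studies-per-MA distribution: `k = 2 + rnbinom(size, mu)`,
#'   a shifted negative binomial with support `{2, 3, ...}`.
#' @param n_dist Per-arm sample-size distribution: a log-normal
#'   (`meanlog`, `sdlog`) for the treatment arm, with the control arm
#'   drawn within 10% of it; sizes are rounded and floored at 2.
#' @param p0_dist Control-risk distribution: `Beta(shape1, shape2)`,
#'   truncated to `[0.01, 0.95]`.
#' @param theta True mean effect on the log odds ratio scale. True study
#'   effects are generated on this scale regardless of the measure later
#'   used for analysis.
#' @param tau2 True between-study variance of the study-specific effects.
#' @param seed Integer seed; together with the MA index it fully
#'   determines every generated table.
#' @return A list of class `synthetic_config`.
#' @examples
#' synthetic_config(n_mas = 10, seed = 42)
#' @export
synthetic_config <- function(n_mas = 100,
                             k_dist = list(size = 1.1, mu = 3.0),
                             n_dist = list(meanlog = log(55), sdlog = 1.2),
                             p0_dist = list(shape1 = 1.4, shape2 = 5.0),
                             theta = -0.5, tau2 = 0.16,
                             seed = 1L) {
  stopifnot(n_mas >= 0, k_dist$size > 0, k_dist$mu > 0, n_dist$sdlog > 0,
            p0_dist$shape1 > 0, p0_dist$shape2 > 0, tau2 >= 0)
  structure(
    list(n_mas = as.integer(n_mas), k_dist = k_dist, n_dist = n_dist,
         p0_dist = p0_dist, theta = theta, tau2 = tau2,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# deterministic per-MA seed below 2^31
ma_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Generate one synthetic meta-analysis
#'
#' Draws the number of studies, per-study arm sizes, control risk and true
#' log odds ratio, inverts the log odds ratio at the control risk to get
#' the treatment risk, and draws binomial event counts. Deterministic
#' given `(config$seed, index)`.
#'
#' @param config A [synthetic_config()].
#' @param index Positive integer identifying the meta-analysis within the
#'   corpus.
#' @return A tibble in the corpus schema (one row per study).
#' @examples
#' generate_ma(synthetic_config(seed = 7), index = 1)
#' @export
generate_ma <- function(config, index = 1L) {
  stopifnot(inherits(config, "synthetic_config"), index >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(ma_seed(config$seed, index))
  k <- 2L + rnbinom(1, size = config$k_dist$size, mu = config$k_dist$mu)
  n1 <- pmax(2L, as.integer(round(rlnorm(k, config$n_dist$meanlog,
                                         config$n_dist$sdlog))))
  n0 <- pmax(2L, as.integer(round(n1 * runif(k, 0.9, 1.1))))
  p0 <- pmin(0.95, pmax(0.01, rbeta(k, config$p0_dist$shape1,
                                    config$p0_dist$shape2)))
  theta_i <- rnorm(k, config$theta, sqrt(config$tau2))
  odds1 <- p0 / (1 - p0) * exp(theta_i)
  p1 <- odds1 / (1 + odds1)
  tibble::tibble(
    ma_id = sprintf("ma_%05d", index),
    study_id = sprintf("ma_%05d_s%02d", index, seq_len(k)),
    e1 = rbinom(k, n1, p1), n1 = n1,
    e0 = rbinom(k, n0, p0), n0 = n0
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic corpus
#'
#' Assembles `config$n_mas` meta-analyses (see [generate_ma()]) into one
#' long-format tibble. The generation manifest (full configuration, seed,
#' corpus dimensions) is attached as attribute `"manifest"` and can be
#' written alongside the corpus by [write_corpus_manifest()].
#'
#' @param config A [synthetic_config()].
#' @return A corpus tibble; zero-row (with the full schema) when
#'   `n_mas = 0`.
#' @examples
#' corpus <- generate_corpus(synthetic_config(n_mas = 5, seed = 1))
#' dplyr::count(corpus, ma_id)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_mas == 0L) {
    out <- tibble::tibble(ma_id = character(), study_id = character(),
                          e1 = integer(), n1 = integer(),
                          e0 = integer(), n0 = integer())
  } else {
    out <- purrr::map_dfr(seq_len(config$n_mas),
                          function(i) generate_ma(config, i))
  }
  attr(out, "manifest") <- corpus_manifest(config, out)
  out
}

corpus_manifest <- function(config, corpus) {
  list(
    generator = "metafrag::generate_corpus",
    config = unclass(config),
    n_mas = config$n_mas,
    n_studies = nrow(corpus),
    total_n = if (nrow(corpus)) sum(corpus$n1 + corpus$n0) else 0,
    total_events = if (nrow(corpus)) sum(corpus$e1 + corpus$e0) else 0
  )
}

#' Write a corpus manifest as JSON
#'
#' @param corpus A corpus generated by [generate_corpus()] (must carry a
#'   `"manifest"` attribute).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_corpus_manifest <- function(corpus, path) {
  man <- attr(corpus, "manifest")
  if (is.null(man)) {
    abort("`corpus` carries no manifest; generate it with generate_corpus().",
          class = "metafrag_bad_data")
  }
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
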