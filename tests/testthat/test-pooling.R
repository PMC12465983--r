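test_that("fixed-effect pooling matches hand-computed weighted means", {
  # identical studies: estimate preserved, se scales by 1/sqrt(2)
  p <- pool_fixed(tibble::tibble(yi = c(0.5, 0.5), sei = c(0.1, 0.1)))
  expect_equal(p$estimate, 0.5, tolerance = 1e-12)
  expect_equal(p$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$q, 0, tolerance = 1e-12)
  # equal weights: plain mean
  p2 <- pool_fixed(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
  expect_equal(p2$estimate, 1, tolerance = 1e-12)
  expect_equal(p2$se, 1 / sqrt(2), tolerance = 1e-12)
  # a single informative study is not poolable
  expect_error(pool_fixed(tibble::tibble(yi = 1, sei = 1)),
               class = "metafrag_too_few_studies")
  expect_error(
    pool_fixed(tibble::tibble(yi = c(1, 2), sei = c(1, 1),
                              informative = c(TRUE, FALSE))),
    class = "metafrag_too_few_studies")
})

test_that("Q statistic and I-squared match hand computation", {
  q <- q_statistic(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
  expect_equal(q$q, 2, tolerance = 1e-10)
  expect_equal(q$df, 1)
  expect_equal(q$p_value, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  q3 <- q_statistic(tibble::tibble(yi = c(0, 1, 2), sei = c(1, 1, 1)))
  expect_equal(q3$q, 2, tolerance = 1e-10)
  expect_equal(q3$df, 2)
  expect_equal(i_squared(2, 1), 0.5)
  expect_equal(i_squared(0.5, 1), 0)   # truncation at Q <= df
  expect_equal(i_squared(0, 1), 0)     # degenerate Q = 0
})

test_that("DL estimator matches hand computation, including truncation", {
  expect_equal(tau2_dl(tibble::tibble(yi = c(0, 2), sei = c(1, 1))), 1,
               tolerance = 1e-10)
  expect_equal(tau2_dl(tibble::tibble(yi = c(0.5, 0.5), sei = c(1, 1))), 0)
  # Q = df boundary truncates to zero
  expect_equal(tau2_dl(tibble::tibble(yi = c(0, 1, 2), sei = c(1, 1, 1))), 0)
})

test_that("REML matches the equal-variance closed form on random instances", {
  r <- tau2_reml(tibble::tibble(yi = c(0, 2), sei = c(1, 1)))
  expect_true(r$converged)
  expect_equal(r$tau2, 1, tolerance = 1e-6)
  r0 <- tau2_reml(tibble::tibble(yi = c(0.7, 0.7, 0.7), sei = c(1, 1, 1)))
  expect_true(r0$converged)
  expect_equal(r0$tau2, 0, tolerance = 1e-10)
  set.seed(7)
  for (i in 1:60) {
    k <- sample(3:12, 1)
    v <- runif(1, 0.05, 1)
    y <- rnorm(k, 0, 1)
    closed <- max(0, var(y) - v)
    r <- tau2_reml(tibble::tibble(yi = y, sei = sqrt(v)))
    expect_true(r$converged)
    expect_equal(r$tau2, closed, tolerance = 1e-6)
  }
})

test_that("random-effects pooling matches hand computation for both CI methods", {
  eff <- tibble::tibble(yi = c(0, 2), sei = c(1, 1))
  # normal method: w* = 1/2 each, se = (sum w*)^(-1/2) = 1
  pn <- pool_random(eff, tau2 = 1, ci_method = "normal")
  expect_equal(pn$estimate, 1, tolerance = 1e-12)
  expect_equal(pn$se, 1, tolerance = 1e-12)
  expect_equal(pn$ci_lo, 1 - qnorm(0.975), tolerance = 1e-10)
  # HKSJ: weighted variance 1, t interval with 1 df
  ph <- pool_random(eff, tau2 = 1, ci_method = "HKSJ")
  expect_equal(ph$estimate, 1, tolerance = 1e-12)
  expect_equal(ph$se, 1, tolerance = 1e-12)
  expect_equal(ph$ci_hi, 1 + qt(0.975, 1), tolerance = 1e-10)
  expect_equal(ph$ci_hi, 1 + 12.7062047, tolerance = 1e-6)
  expect_false(ph$degenerate)
  # identical studies: zero HKSJ variance is flagged, not patched
  pd <- pool_random(tibble::tibble(yi = c(1, 1), sei = c(1, 1)),
                    tau2 = 0, ci_method = "HKSJ")
  expect_true(pd$degenerate)
  expect_equal(pd$se, 0)
})

test_that("RE with tau2 = 0 reproduces the FE estimate and normal-method se", {
  set.seed(11)
  for (i in 1:10) {
    eff <- sim_effects(sample(3:8, 1))
    fe <- pool_fixed(eff)
    re <- pool_random(eff, tau2 = 0, ci_method = "normal")
    expect_equal(re$estimate, fe$estimate, tolerance = 1e-12)
    expect_equal(re$se, fe$se, tolerance = 1e-12)
  }
})

test_that("tau2 estimators are translation invariant; Q and I2 are scale free", {
  set.seed(12)
  for (i in 1:10) {
    eff <- sim_effects(sample(3:8, 1))
    shifted <- dplyr::mutate(eff, yi = yi + 3.7)
    expect_equal(tau2_dl(eff), tau2_dl(shifted), tolerance = 1e-10)
    expect_equal(tau2_reml(eff)$tau2, tau2_reml(shifted)$tau2,
                 tolerance = 1e-6)
    scaled <- dplyr::mutate(eff, yi = yi * 2.5, sei = sei * 2.5)
    expect_equal(q_statistic(eff)$q, q_statistic(scaled)$q,
                 tolerance = 1e-10)
    fe1 <- pool_fixed(eff); fe2 <- pool_fixed(scaled)
    expect_equal(fe1$i2, fe2$i2, tolerance = 1e-10)
  }
})

test_that("pooling agrees with metafor across scenarios", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:8) {
    ma <- rand_small_ma()
    eff <- study_effects(ma, "OR")
    if (any(!eff$informative)) next
    for (scn in c("FE", "S1", "S2", "S3", "S4")) {
      mine <- meta_pool(ma, scn, "OR")
      if (!mine$converged) next
      ref <- switch(scn,
        FE = metafor::rma.uni(yi = eff$yi, sei = eff$sei, method = "FE"),
        S1 = metafor::rma.uni(yi = eff$yi, sei = eff$sei, method = "REML",
                              test = "knha"),
        S2 = metafor::rma.uni(yi = eff$yi, sei = eff$sei, method = "REML"),
        S3 = metafor::rma.uni(yi = eff$yi, sei = eff$sei, method = "DL",
                              test = "knha"),
        S4 = metafor::rma.uni(yi = eff$yi, sei = eff$sei, method = "DL"))
      expect_equal(mine$estimate, as.numeric(ref$beta), tolerance = 1e-4)
      expect_equal(mine$se, ref$se, tolerance = 1e-4)
      expect_equal(mine$tau2, ref$tau2, tolerance = 1e-3)
      expect_equal(mine$p_value, ref$pval, tolerance = 1e-3)
    }
  }
})

test_that("REML non-convergence is a reported state with a tight iteration cap", {
  set.seed(4)
  eff <- sim_effects(5)
  r <- tau2_reml(eff, maxit = 1L, tol = 1e-14)
  expect_false(r$converged)
  expect_true(is.na(r$tau2))
})

test_that("meta_pool significance verdict follows the interval", {
  expect_equal(assess_significance(list(ci_lo = 0.1, ci_hi = 0.5)),
               "significant")
  expect_equal(assess_significance(list(ci_lo = -0.1, ci_hi = 0.5)),
               "nonsignificant")
  expect_equal(assess_significance(list(ci_lo = -0.5, ci_hi = -0.1)),
               "significant")
  fit <- meta_pool(fixture_f1(), "FE", "OR")
  expect_identical(assess_significance(fit),
                   if (fit$significant) "significant" else "nonsignificant")
  expect_identical(fit$significant, fit$p_value < 0.05)
})

test_that("tidy and glance methods return well-formed tibbles", {
  fit <- meta_pool(fixture_f1(), "S4", "OR")
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("scenario", "measure", "estimate", "se", "ci_lo",
                     "ci_hi", "p_value", "tau2", "q", "q_df", "q_p", "i2",
                     "k", "converged", "degenerate", "significant"))
})
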