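test_that("scenario pairs coincide when both tau2 estimates are zero", {
  # identical studies: DL and REML both estimate tau2 = 0, so S1 == S3 and
  # S2 == S4 exactly
  ma <- tibble::tibble(e1 = c(12, 12), n1 = c(20, 20),
                       e0 = c(4, 4), n0 = c(20, 20))
  res <- run_scenarios(ma, measures = "OR", fi = "none")
  s <- function(x) res[res$scenario == x, ]
  for (col in c("estimate", "se", "ci_lo", "ci_hi", "tau2")) {
    expect_identical(s("S1")[[col]], s("S3")[[col]])
    expect_identical(s("S2")[[col]], s("S4")[[col]])
  }
  expect_equal(s("S1")$tau2, 0)
  # with zero dispersion the HKSJ variance is degenerate
  expect_true(s("S1")$degenerate)
  expect_false(s("S2")$degenerate)
})

test_that("S2 and S4 share the normal CI machinery and differ only via tau2", {
  set.seed(8)
  ma <- rand_small_ma()
  res <- run_scenarios(ma, measures = "OR", scenarios = c("S2", "S4"),
                       fi = "none")
  eff <- study_effects(ma, "OR")
  for (i in 1:2) {
    row <- res[i, ]
    pr <- pool_random(eff, tau2 = row$tau2, ci_method = "normal")
    expect_equal(row$estimate, pr$estimate, tolerance = 1e-10)
    expect_equal(row$se, pr$se, tolerance = 1e-10)
  }
})

test_that("run_scenarios produces five result records per measure for F1", {
  res <- run_scenarios(fixture_f1(), measures = "OR", fi = "all", cap = 10)
  expect_equal(nrow(res), 5)
  expect_setequal(res$scenario, c("FE", "S1", "S2", "S3", "S4"))
  # frozen regression (oracle-validated in test-fragility.R)
  expect_equal(res$fi[match(c("FE", "S1", "S2", "S3", "S4"), res$scenario)],
               c(5L, 1L, 3L, 1L, 3L))
  expect_true(all(res$converged))
  expect_equal(res$total_n, rep(80, 5))
})

test_that("sample-size and event bins follow the half-open boundary convention", {
  expect_equal(as.character(bin_sample_size(c(49, 50, 100, 723, 999, 1000))),
               c("<50", "50-100", "100-200", "500-1000", "500-1000",
                 ">=1000"))
  expect_equal(as.character(bin_events(c(9, 10, 50, 130, 1000, 4000))),
               c("<10", "10-50", "50-100", "100-500", ">=1000", ">=1000"))
  # every positive value lands in exactly one bin
  set.seed(3)
  x <- sample(1:5000, 200)
  expect_false(any(is.na(bin_sample_size(x))))
  expect_false(any(is.na(bin_events(x))))
})

test_that("I2 bands overlap per the guideline ranges and strata do not", {
  expect_setequal(i2_bands(0.35), c("not-important", "moderate"))
  expect_setequal(i2_bands(0), "not-important")
  expect_setequal(i2_bands(0.4), c("not-important", "moderate"))
  expect_setequal(i2_bands(0.8), c("substantial", "considerable"))
  expect_setequal(i2_bands(1), "considerable")
  # no value is band-less
  for (v in seq(0, 1, by = 0.05)) expect_gte(length(i2_bands(v)), 1)
  st <- i2_stratum(c(0, 0.39, 0.4, 0.6, 0.75, 1))
  expect_equal(as.character(st),
               c("[0,0.4)", "[0,0.4)", "[0.4,0.6)", "[0.6,0.75)",
                 "[0.75,1]", "[0.75,1]"))
})

test_that("effect-magnitude bands invert sub-unit ratios and use half-open cutoffs", {
  expect_equal(as.character(or_magnitude(c(0.4, 1, 1.68, 3.47, 6.71, 7))),
               c("moderate", "small", "moderate", "medium", "large",
                 "large"))
  expect_equal(as.character(rr_magnitude(c(1, 1.22, 1.86, 2.99, 3, 1 / 3))),
               c("small", "moderate", "medium", "medium", "large", "large"))
  # inversion symmetry
  set.seed(6)
  v <- exp(rnorm(50))
  expect_identical(or_magnitude(v), or_magnitude(1 / v))
})

test_that("corpus summaries compute medians and proportions on the significant subset", {
  res <- tibble::tibble(
    ma_id = paste0("m", 1:6), measure = "OR", scenario = "S1",
    k = 3, total_n = c(40, 80, 700, 1200, 90, 60),
    total_events = c(10, 20, 100, 400, 30, 15),
    estimate = 1, se = 0.2, ci_lo = c(rep(0.5, 5), -0.2),
    ci_hi = c(rep(1.5, 5), 0.2), ci_len = 1, p_value = 0.01, tau2 = 0,
    q = 1, i2 = 0, converged = TRUE, degenerate = FALSE,
    significant = c(rep(TRUE, 5), FALSE),
    fi = c(1L, 3L, 5L, 7L, 9L, 2L), fi_attainable = TRUE,
    fq = c(1, 3, 5, 7, 9, 2) / c(40, 80, 700, 1200, 90, 60),
    fi_direction = "toward_null"
  )
  sm <- summarize_corpus(res)
  ov <- sm$overall
  expect_equal(ov$n_significant, 5)
  expect_equal(ov$fi_median, 5)          # median of 1,3,5,7,9
  expect_equal(ov$prop_fi_le5, 0.6)
  expect_equal(ov$prop_fi_1, 0.2)
  expect_gte(ov$prop_fi_le5, ov$prop_fi_1)
  expect_error(summarize_corpus(res[0, ]), class = "metafrag_bad_data")
  # single significant MA with FI = 1
  sm1 <- summarize_corpus(res[1, ])
  expect_equal(sm1$overall$prop_fi_1, 1)
})

test_that("paired differences subtract scenario FIs and CI lengths per MA", {
  res <- tibble::tibble(
    ma_id = rep(c("a", "b", "c"), 2), measure = "OR",
    scenario = rep(c("S3", "S1"), each = 3),
    fi = c(6L, 4L, NA, 4L, 4L, 2L), fi_attainable = c(TRUE, TRUE, FALSE,
                                                      TRUE, TRUE, TRUE),
    ci_len = c(2, 2.4, 3, 1.5, 2.4, 1)
  )
  pd <- paired_differences(res, "S3", "S1")
  expect_equal(pd$fi_diff, c(2, 0))
  expect_equal(pd$ci_len_diff, c(0.5, 0))
  expect_equal(attr(pd, "n_excluded"), 1)
  # identical scenarios give zero differences
  pd0 <- paired_differences(res, "S1", "S1")
  expect_true(all(pd0$fi_diff == 0))
})
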