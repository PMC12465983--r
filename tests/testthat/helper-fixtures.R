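# Shared fixtures and generators (all built in code).

# two-study meta-analysis used as a frozen regression fixture
fixture_f1 <- function() {
  tibble::tibble(
    ma_id = "f1", study_id = c("s1", "s2"),
    e1 = c(12, 11), n1 = c(20, 20), e0 = c(4, 5), n0 = c(20, 20)
  )
}

# random small meta-analysis (2-4 studies, arm sizes <= 25)
rand_small_ma <- function() {
  k <- sample(2:4, 1)
  n1 <- sample(5:25, k, replace = TRUE)
  n0 <- sample(5:25, k, replace = TRUE)
  tibble::tibble(
    e1 = rbinom(k, n1, runif(k, 0.1, 0.7)), n1 = n1,
    e0 = rbinom(k, n0, runif(k, 0.1, 0.7)), n0 = n0
  )
}

# effect-level simulation with known standard errors
sim_effects <- function(k, theta = 0.5, tau2 = 0.1,
                        smin = 0.1, smax = 0.3) {
  s <- runif(k, smin, smax)
  tibble::tibble(yi = rnorm(k, theta, sqrt(tau2 + s^2)), sei = s)
}

fi_or_na <- function(frag) {
  if (frag$attainable) frag$fi else NA_integer_
}

# file contents as a comparable string (byte-identity checks)
digest_file <- function(f) {
  paste(as.character(readBin(f, "raw", file.size(f))), collapse = "")
}

# apply one row of a fragility plan to a counts data frame
within_flip <- function(cnt, plan_row) {
  col <- if (plan_row$arm == 1L) "e1" else "e0"
  cnt[[col]][plan_row$study] <- cnt[[col]][plan_row$study] + plan_row$delta
  cnt
}
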