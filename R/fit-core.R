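# Vectorised numerical core.
#
# Everything here operates on S x k matrices: S candidate count
# configurations (rows) of the same k-study meta-analysis.  The fragility
# search evaluates thousands of single-flip variants of one dataset per
# step, so all pooling machinery is written to run across rows at once.
# Cells excluded from analysis (double-zero studies under OR/RR) carry NA
# and are dropped via na.rm sums.

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Study-level effects on the analysis scale for each row configuration.
# Returns list(y, s2, corrected, informative); y/s2 are NA at
# non-informative cells.
effects_core <- function(E1, N1, E0, N0, measure,
                         correction = "zero-cells",
                         double_zero = "exclude") {
  E1 <- as_row_matrix(E1); N1 <- as_row_matrix(N1)
  E0 <- as_row_matrix(E0); N0 <- as_row_matrix(N0)
  S <- nrow(E1); k <- ncol(E1)
  zero <- E1 == 0 | E1 == N1 | E0 == 0 | E0 == N0
  docorr <- if (identical(correction, "none")) matrix(FALSE, S, k) else zero
  half <- 0.5 * docorr
  a <- E1 + half
  b <- (N1 - E1) + half
  cc <- E0 + half
  d <- (N0 - E0) + half
  m1 <- N1 + docorr
  m0 <- N0 + docorr
  informative <- matrix(TRUE, S, k)
  if (measure %in% c("OR", "RR") && identical(double_zero, "exclude")) {
    informative <- !(E1 == 0 & E0 == 0)
  }
  if (measure == "OR") {
    y <- log((a * d) / (b * cc))
    s2 <- 1 / a + 1 / b + 1 / cc + 1 / d
  } else if (measure == "RR") {
    y <- log((a / m1) / (cc / m0))
    s2 <- 1 / a - 1 / m1 + 1 / cc - 1 / m0
  } else if (measure == "RD") {
    p1 <- a / m1
    p0 <- cc / m0
    y <- p1 - p0
    s2 <- p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0
  } else {
    abort(paste0("Unknown effect measure: ", measure),
          class = "metafrag_bad_config")
  }
  y[!informative] <- NA_real_
  s2[!informative] <- NA_real_
  list(y = y, s2 = s2, corrected = docorr & informative,
       informative = informative)
}

# DL method-of-moments tau^2 per row, from FE weights.
tau2_dl_core <- function(y, s2) {
  w <- 1 / s2
  sw <- rowSums(w, na.rm = TRUE)
  theta <- rowSums(w * y, na.rm = TRUE) / sw
  Q <- rowSums(w * (y - theta)^2, na.rm = TRUE)
  kinf <- rowSums(!is.na(y))
  den <- sw - rowSums(w^2, na.rm = TRUE) / sw
  t2 <- (Q - (kinf - 1)) / den
  pmax(0, ifelse(den > 0, t2, 0))
}

# REML tau^2 per row via the standard fixed-point iteration
#   tau2 <- sum(w^2 ((y - theta)^2 - s2)) / sum(w^2) + 1 / sum(w),
# w = 1/(s2 + tau2), truncated at 0, started at the DL estimate.
# Returns list(tau2, converged, iterations); rows that do not meet `tol`
# within `maxit` get converged = FALSE and tau2 = NA.
tau2_reml_core <- function(y, s2, tol = 1e-8, maxit = 100L,
                           start = NULL) {
  S <- nrow(y)
  t2 <- if (is.null(start)) tau2_dl_core(y, s2) else rep_len(start, S)
  conv <- rep(FALSE, S)
  iters <- rep(0L, S)
  for (it in seq_len(maxit)) {
    idx <- which(!conv)
    if (length(idx) == 0L) break
    yi <- y[idx, , drop = FALSE]
    s2i <- s2[idx, , drop = FALSE]
    w <- 1 / (s2i + t2[idx])   # matrix + per-row vector (column-major recycle)
    sw <- rowSums(w, na.rm = TRUE)
    theta <- rowSums(w * yi, na.rm = TRUE) / sw
    num <- rowSums(w^2 * ((yi - theta)^2 - s2i), na.rm = TRUE)
    den <- rowSums(w^2, na.rm = TRUE)
    t2new <- pmax(0, num / den + 1 / sw)
    done <- is.finite(t2new) & abs(t2new - t2[idx]) < tol
    t2[idx] <- t2new
    iters[idx] <- it
    conv[idx[done]] <- TRUE
  }
  t2[!conv] <- NA_real_
  list(tau2 = t2, converged = conv, iterations = iters)
}

# Full pooled fit for every row.  `spec` is a scenario_spec.
# Returns a list of length-S vectors.
pool_core <- function(y, s2, spec) {
  y <- as_row_matrix(y); s2 <- as_row_matrix(s2)
  S <- nrow(y)
  seen <- !is.na(y) | !is.na(s2)
  ok_cell <- seen & is.finite(y) & is.finite(s2) & s2 > 0
  degenerate_study <- rowSums(seen & !ok_cell) > 0
  y[!ok_cell] <- NA_real_
  s2[!ok_cell] <- NA_real_
  kinf <- rowSums(ok_cell)
  usable <- kinf >= 2L & !degenerate_study

  w <- 1 / s2
  sw <- rowSums(w, na.rm = TRUE)
  theta_fe <- rowSums(w * y, na.rm = TRUE) / sw
  Q <- rowSums(w * (y - theta_fe)^2, na.rm = TRUE)
  df <- kinf - 1L
  Qp <- ifelse(df >= 1, pchisq(Q, pmax(df, 1L), lower.tail = FALSE), NA_real_)
  I2 <- ifelse(Q > 0, pmax(0, (Q - df) / Q), 0)

  converged <- rep(TRUE, S)
  if (spec$model == "FE") {
    tau2 <- rep(0, S)
    wp <- w
  } else {
    if (spec$tau2_method == "DL") {
      tau2 <- tau2_dl_core(y, s2)
    } else {
      rem <- tau2_reml_core(y, s2, tol = spec$reml_tol,
                            maxit = spec$reml_maxit)
      tau2 <- rem$tau2
      converged <- rem$converged
    }
    wp <- 1 / (s2 + tau2)  # NA tau2 rows propagate NA below
  }
  swp <- rowSums(wp, na.rm = TRUE)
  est <- rowSums(wp * y, na.rm = TRUE) / swp
  degenerate_var <- rep(FALSE, S)
  if (spec$ci_method == "HKSJ" && spec$model == "RE") {
    qh <- rowSums(wp * (y - est)^2, na.rm = TRUE) / pmax(df, 1L)
    vhk <- qh / swp
    degenerate_var <- usable & converged & vhk <= 0
    se <- sqrt(vhk)
    crit <- qt(1 - spec$alpha / 2, pmax(df, 1L))
    tstat <- abs(est) / se
    p <- 2 * pt(-tstat, pmax(df, 1L))
    p[which(se == 0 & abs(est) > 0)] <- 0
    p[which(se == 0 & est == 0)] <- 1
  } else {
    se <- sqrt(1 / swp)
    crit <- qnorm(1 - spec$alpha / 2)
    p <- 2 * pnorm(-abs(est) / se)
  }
  ci_lo <- est - crit * se
  ci_hi <- est + crit * se

  drop <- !usable | (is.na(tau2) & spec$model == "RE")
  for (nm in c("est", "se", "ci_lo", "ci_hi", "p", "tau2")) {
    v <- get(nm)
    v[drop] <- NA_real_
    assign(nm, v)
  }
  list(est = est, se = se, ci_lo = ci_lo, ci_hi = ci_hi, p = p,
       tau2 = tau2, tau = sqrt(tau2), Q = Q, Q_df = df, Q_p = Qp, I2 = I2,
       k = kinf, usable = usable, converged = converged,
       degenerate_var = degenerate_var)
}

# counts -> pooled fit, re-resolving continuity corrections per row
fit_counts_core <- function(E1, N1, E0, N0, spec) {
  eff <- effects_core(E1, N1, E0, N0, spec$measure,
                      correction = spec$correction,
                      double_zero = spec$double_zero)
  out <- pool_core(eff$y, eff$s2, spec)
  out$corrected_any <- rowSums(eff$corrected) > 0
  out
}

# significance verdict: interval excludes the null (0 on the analysis scale)
sig_core <- function(ci_lo, ci_hi) {
  !is.na(ci_lo) & !is.na(ci_hi) & (ci_lo > 0 | ci_hi < 0)
}
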