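# Fragility of a meta-analysis: minimum number of single-patient
# event-status modifications that alters the significance verdict.
#
# A single modification changes one patient's event status in one arm of
# one study, i.e. moves that arm's event count by +/-1 within [0, n].
# After every (candidate) modification the full scenario is re-fitted from
# the raw counts: continuity corrections are re-resolved and tau2
# re-estimated, because flips can create or remove zero cells.

new_fragility <- function(fi, attainable, direction, plan, trail, p0, sig0,
                          total_n, cap, method, spec) {
  fq <- if (attainable) fi / total_n else NA_real_
  structure(
    list(fi = if (attainable) as.integer(fi) else NA_integer_,
         attainable = attainable, fq = fq, direction = direction,
         plan = plan, trail = trail, p0 = p0,
         initial_verdict = if (sig0) "significant" else "nonsignificant",
         total_n = total_n, cap = as.integer(cap), method = method,
         spec = spec),
    class = "fragility"
  )
}

empty_plan <- function() {
  tibble::tibble(step = integer(), study = integer(), study_id = character(),
                 arm = integer(), delta = integer(), p_after = double())
}

# Flip moves from a state vector c(e1, e0).  `push` = +1 keeps only moves
# that raise the pooled estimate (add a treatment event / remove a control
# event), `push` = -1 the mirror, `push` = NULL all four flip types per
# study.  Generation order (study ascending, arm 1 before arm 0, +1
# before -1) is the deterministic tie-break.
flip_moves <- function(state, n1, n0, push = NULL) {
  k <- length(n1)
  e1 <- state[seq_len(k)]
  e0 <- state[k + seq_len(k)]
  out <- vector("list", k)
  for (i in seq_len(k)) {
    mv <- list()
    up1 <- e1[i] < n1[i]; dn1 <- e1[i] > 0
    up0 <- e0[i] < n0[i]; dn0 <- e0[i] > 0
    if (is.null(push)) {
      if (up1) mv[[length(mv) + 1L]] <- c(i, 1L, 1L)
      if (dn1) mv[[length(mv) + 1L]] <- c(i, 1L, -1L)
      if (up0) mv[[length(mv) + 1L]] <- c(i, 0L, 1L)
      if (dn0) mv[[length(mv) + 1L]] <- c(i, 0L, -1L)
    } else if (push > 0) {
      if (up1) mv[[length(mv) + 1L]] <- c(i, 1L, 1L)
      if (dn0) mv[[length(mv) + 1L]] <- c(i, 0L, -1L)
    } else {
      if (dn1) mv[[length(mv) + 1L]] <- c(i, 1L, -1L)
      if (up0) mv[[length(mv) + 1L]] <- c(i, 0L, 1L)
    }
    out[[i]] <- mv
  }
  m <- do.call(rbind, unlist(out, recursive = FALSE))
  if (is.null(m)) m <- matrix(integer(0), 0, 3)
  colnames(m) <- c("study", "arm", "delta")
  m
}

apply_flip <- function(cnt, study, arm, delta) {
  col <- if (arm == 1L) "e1" else "e0"
  cnt[[col]][study] <- cnt[[col]][study] + delta
  cnt
}

move_to_state <- function(state, move, k) {
  j <- if (move[2] == 1L) move[1] else k + move[1]
  state[j] <- state[j] + move[3]
  state
}

fit_states <- function(states, n1, n0, spec) {
  k <- length(n1)
  fit_counts_core(states[, seq_len(k), drop = FALSE],
                  matrix(n1, nrow(states), k, byrow = TRUE),
                  states[, k + seq_len(k), drop = FALSE],
                  matrix(n0, nrow(states), k, byrow = TRUE), spec)
}

state_keys <- function(m) do.call(paste, c(as.data.frame(m), sep = ","))

# Layered beam search for the minimum flip count.  At each depth every
# retained state is expanded by its admissible moves, duplicates and
# previously seen states are dropped, all new states are re-fitted from
# raw counts in one vectorised batch, and the `beam` states whose p-value
# lies furthest toward the significance boundary are kept.  The search
# stops at the first depth at which some state alters the verdict; the
# returned plan is the move path to that state.  Beam width 1 is the
# classical one-step greedy; wider beams guard against locally optimal
# flips that corrections or the HKSJ variance make globally wasteful.
beam_run <- function(cnt0, spec, cap, sig0, push, beam) {
  k <- nrow(cnt0)
  n1 <- cnt0$n1; n0 <- cnt0$n0
  base <- c(cnt0$e1, cnt0$e0)
  states <- matrix(base, nrow = 1)
  plans <- list(matrix(integer(0), 0, 3))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_keys(states), TRUE, envir = visited)
  for (depth in seq_len(cap)) {
    cand_states <- list()
    cand_plans <- list()
    for (b in seq_len(nrow(states))) {
      mv <- flip_moves(states[b, ], n1, n0, push)
      if (nrow(mv) == 0) next
      ns <- t(vapply(seq_len(nrow(mv)),
                     function(j) move_to_state(states[b, ], mv[j, ], k),
                     numeric(2L * k)))
      cand_states[[b]] <- ns
      cand_plans[[b]] <- lapply(seq_len(nrow(mv)),
                                function(j) rbind(plans[[b]], mv[j, ]))
    }
    if (length(cand_states) == 0) break
    cs <- do.call(rbind, cand_states)
    cp <- unlist(cand_plans, recursive = FALSE)
    keys <- state_keys(cs)
    keep <- !duplicated(keys)
    keep[keep] <- !vapply(keys[keep], exists, logical(1), envir = visited,
                          USE.NAMES = FALSE)
    if (!any(keep)) break
    cs <- cs[keep, , drop = FALSE]
    cp <- cp[keep]
    for (kk in keys[keep]) assign(kk, TRUE, envir = visited)
    fit <- fit_states(cs, n1, n0, spec)
    valid <- fit$usable & fit$converged & !is.na(fit$p)
    if (!any(valid)) break
    flipped <- valid & sig_core(fit$ci_lo, fit$ci_hi) != sig0
    if (any(flipped)) {
      sc <- fit$p
      sc[!flipped] <- if (sig0) -Inf else Inf
      win <- if (sig0) which.max(sc) else which.min(sc)
      return(list(fi = depth, plan = cp[[win]]))
    }
    sc <- fit$p
    sc[!valid] <- if (sig0) -Inf else Inf
    ord <- if (sig0) order(-sc, seq_along(sc)) else order(sc, seq_along(sc))
    sel <- ord[seq_len(min(beam, sum(valid)))]
    states <- cs[sel, , drop = FALSE]
    plans <- cp[sel]
  }
  list(fi = NA_integer_, plan = NULL)
}

# Exhaustive breadth-first enumeration of modification multisets by total
# size 1..cap (unrestricted flips, deduplicated by resulting counts).
# Returns list(fi, delta) with delta the count change achieving the flip,
# or fi = NA when nothing within cap alters the verdict.
bfs_min_flips <- function(cnt0, spec, cap, sig0) {
  k <- nrow(cnt0)
  n1 <- cnt0$n1; n0 <- cnt0$n0
  base <- c(cnt0$e1, cnt0$e0)
  lo <- rep(0L, 2L * k)
  hi <- c(n1, n0)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_keys(matrix(base, 1)), TRUE, envir = visited)
  frontier <- matrix(base, nrow = 1)
  expand <- function(frontier) {
    S <- nrow(frontier); d <- ncol(frontier)
    reps <- frontier[rep(seq_len(S), each = 2L * d), , drop = FALSE]
    shift <- matrix(0L, 2L * d, d)
    shift[cbind(seq_len(2L * d), rep(seq_len(d), each = 2L))] <- c(1L, -1L)
    out <- reps + shift[rep(seq_len(2L * d), times = S), , drop = FALSE]
    inb <- rowSums(sweep(out, 2, lo, `<`)) == 0 &
      rowSums(sweep(out, 2, hi, `>`)) == 0
    out[inb, , drop = FALSE]
  }
  for (m in seq_len(cap)) {
    cand <- expand(frontier)
    if (nrow(cand) == 0) break
    keys <- state_keys(cand)
    first <- !duplicated(keys)
    cand <- cand[first, , drop = FALSE]
    keys <- keys[first]
    new <- !vapply(keys, exists, logical(1), envir = visited,
                   USE.NAMES = FALSE)
    cand <- cand[new, , drop = FALSE]
    keys <- keys[new]
    if (nrow(cand) == 0) break
    for (kk in keys) assign(kk, TRUE, envir = visited)
    fit <- fit_states(cand, n1, n0, spec)
    flip <- fit$usable & fit$converged &
      sig_core(fit$ci_lo, fit$ci_hi) != sig0
    if (any(flip)) {
      win <- which(flip)[1L]
      return(list(fi = m, delta = cand[win, ] - base))
    }
    frontier <- cand
  }
  list(fi = NA_integer_, delta = NULL)
}

# moves matrix (study, arm, delta unit flips) from a count-change vector,
# ordered by study then arm 1 before arm 0
delta_to_moves <- function(delta, k) {
  steps <- list()
  for (i in seq_len(k)) {
    d1 <- delta[i]
    d0 <- delta[k + i]
    if (d1 != 0) for (j in seq_len(abs(d1))) {
      steps[[length(steps) + 1L]] <- c(i, 1L, sign(d1))
    }
    if (d0 != 0) for (j in seq_len(abs(d0))) {
      steps[[length(steps) + 1L]] <- c(i, 0L, sign(d0))
    }
  }
  do.call(rbind, steps)
}

# turn a move matrix into the plan tibble, re-fitting after each applied
# move for the p-value trail
plan_tibble <- function(cnt0, moves, spec) {
  if (is.null(moves) || nrow(moves) == 0) return(empty_plan())
  cnt <- cnt0
  p_after <- double(nrow(moves))
  for (s in seq_len(nrow(moves))) {
    cnt <- apply_flip(cnt, moves[s, 1], moves[s, 2], moves[s, 3])
    fit <- fit_counts_core(matrix(cnt$e1, 1), matrix(cnt$n1, 1),
                           matrix(cnt$e0, 1), matrix(cnt$n0, 1), spec)
    p_after[s] <- fit$p
  }
  tibble::tibble(step = seq_len(nrow(moves)),
                 study = as.integer(moves[, 1]),
                 study_id = cnt0$study_id[moves[, 1]],
                 arm = as.integer(moves[, 2]),
                 delta = as.integer(moves[, 3]),
                 p_after = p_after)
}

#' Fragility index of a meta-analysis (greedy beam search)
#'
#' Finds the minimum number of event-status modifications that alters the
#' significance of the pooled effect under the given scenario, by a greedy
#' layered search: at each step every admissible single-patient flip of
#' every retained search state is evaluated with a full scenario re-fit
#' (continuity corrections re-resolved, between-study variance
#' re-estimated), and the `beam` states whose p-values lie furthest toward
#' the significance boundary are carried to the next step. For an
#' initially significant result the admissible flips shift the estimate
#' toward the null (for a positive pooled effect: remove a treatment-arm
#' event or add a control-arm event; mirrored otherwise), so every plan
#' step moves the estimate toward 0. For an initially nonsignificant
#' result all four flip types per study are admissible and the search
#' reaches whichever significance boundary is closer.
#'
#' @inheritParams meta_pool
#' @param cap Maximum number of modifications to try before declaring the
#'   index not attainable. Default: twice the total event count (at least
#'   1).
#' @param beam Number of candidate states retained per search step.
#'   `beam = 1` is classical one-step greedy; the default retains enough
#'   states to escape locally optimal flips that continuity corrections or
#'   the HKSJ variance make globally wasteful. Corpus-scale drivers such
#'   as [run_scenarios()] use a narrower beam for speed.
#' @return An object of class `fragility`: `fi` (integer, or `NA` with
#'   `attainable = FALSE`), `fq` = `fi` divided by the total sample size,
#'   `direction` (`"toward_null"` or `"toward_significance"`), the ordered
#'   modification `plan` with per-step p-values, and the scenario used.
#' @seealso [fragility_ma_exact()] for the exhaustive oracle,
#'   [fragility_study()] for a single trial.
#' @examples
#' ma <- tibble::tibble(
#'   e1 = c(12, 11), n1 = c(20, 20), e0 = c(4, 5), n0 = c(20, 20)
#' )
#' fragility_ma(ma, scenario = "FE", measure = "OR")
#' @export
fragility_ma <- function(data, scenario = "S1", measure = "OR",
                         alpha = 0.05, cap = NULL, beam = 30L, ...) {
  spec <- as_scenario_spec(scenario, measure = measure, alpha = alpha, ...)
  data <- one_ma(data)
  cnt0 <- data
  total_n <- sum(data$n1 + data$n0)
  if (is.null(cap)) cap <- max(1L, 2L * sum(data$e1 + data$e0))
  fit0 <- fit_counts_core(matrix(cnt0$e1, 1), matrix(cnt0$n1, 1),
                          matrix(cnt0$e0, 1), matrix(cnt0$n0, 1), spec)
  if (!fit0$usable) {
    abort("At least 2 informative studies are required.",
          class = "metafrag_too_few_studies")
  }
  if (!fit0$converged) {
    abort("REML did not converge for this dataset; no fragility index under this scenario.",
          class = "metafrag_nonconvergent")
  }
  sig0 <- sig_core(fit0$ci_lo, fit0$ci_hi)
  if (sig0) {
    # primary run: flips that move the estimate toward the null.  A second,
    # unrestricted run guards against the rare shorter plans that work
    # through the variance instead (a "wrong-direction" flip can create a
    # zero cell whose continuity correction inflates the standard error).
    push <- if (fit0$est > 0) -1L else 1L
    run_dir <- beam_run(cnt0, spec, cap, sig0 = TRUE, push = push,
                        beam = beam)
    run_wide <- beam_run(cnt0, spec, cap, sig0 = TRUE, push = NULL,
                         beam = beam)
    dir_wins <- is.na(run_wide$fi) ||
      (!is.na(run_dir$fi) && run_dir$fi <= run_wide$fi)
    run <- if (dir_wins) run_dir else run_wide
    candidates <- if (dir_wins) "directional" else "widened"
    direction <- "toward_null"
  } else {
    run <- beam_run(cnt0, spec, cap, sig0 = FALSE, push = NULL, beam = beam)
    candidates <- "widened"
    direction <- "toward_significance"
  }
  # On small instances a cap-exhausted beam is re-checked exhaustively, so
  # "not attainable" is never a beam-pruning artefact where enumeration is
  # affordable (the state space grows combinatorially, hence the guards).
  if (is.na(run$fi) && nrow(cnt0) <= 5L && cap <= 6L) {
    ex <- bfs_min_flips(cnt0, spec, cap, sig0)
    if (!is.na(ex$fi)) {
      run <- list(fi = ex$fi, plan = delta_to_moves(ex$delta, nrow(cnt0)))
      candidates <- "exhaustive"
    }
  }
  plan <- plan_tibble(cnt0, run$plan, spec)
  out <- new_fragility(run$fi, attainable = !is.na(run$fi),
                       direction = direction, plan = plan,
                       trail = plan$p_after, p0 = fit0$p, sig0 = sig0,
                       total_n = total_n, cap = cap, method = "greedy",
                       spec = spec)
  out$candidates <- candidates
  out
}

#' Fragility index of a meta-analysis (exact breadth-first oracle)
#'
#' Exhaustively enumerates all modification multisets of total size 1, 2,
#' ..., `cap` (flips in any direction, any arm, any study, deduplicated by
#' resulting count configuration) and returns the first size at which some
#' configuration alters the significance verdict — the true minimum. By
#' construction no flip set of smaller size alters the verdict. Intended
#' for small instances; the state space grows combinatorially with `cap`
#' and the number of studies.
#'
#' @inheritParams fragility_ma
#' @param cap Maximum modification-set size to enumerate (default 8).
#' @return A `fragility` object (see [fragility_ma()]); `method = "exact"`.
#' @export
fragility_ma_exact <- function(data, scenario = "S1", measure = "OR",
                               alpha = 0.05, cap = 8L, ...) {
  spec <- as_scenario_spec(scenario, measure = measure, alpha = alpha, ...)
  data <- one_ma(data)
  k <- nrow(data)
  total_n <- sum(data$n1 + data$n0)
  fit0 <- fit_counts_core(matrix(data$e1, 1), matrix(data$n1, 1),
                          matrix(data$e0, 1), matrix(data$n0, 1), spec)
  if (!fit0$usable) {
    abort("At least 2 informative studies are required.",
          class = "metafrag_too_few_studies")
  }
  if (!fit0$converged) {
    abort("REML did not converge for this dataset.",
          class = "metafrag_nonconvergent")
  }
  sig0 <- sig_core(fit0$ci_lo, fit0$ci_hi)
  res <- bfs_min_flips(data, spec, cap, sig0)
  direction <- if (sig0) "toward_null" else "toward_significance"
  if (is.na(res$fi)) {
    return(new_fragility(NA, attainable = FALSE, direction = direction,
                         plan = empty_plan(), trail = double(),
                         p0 = fit0$p, sig0 = sig0, total_n = total_n,
                         cap = cap, method = "exact", spec = spec))
  }
  plan <- plan_tibble(data, delta_to_moves(res$delta, k), spec)
  new_fragility(res$fi, attainable = TRUE, direction = direction,
                plan = plan, trail = plan$p_after, p0 = fit0$p,
                sig0 = sig0, total_n = total_n, cap = cap,
                method = "exact", spec = spec)
}

#' Fragility index of a single study
#'
#' Minimum number of event-status modifications of one two-arm trial that
#' alters the significance of its per-study test (default: two-sided
#' Fisher exact test). Modification sets `(d1, d0)` are enumerated
#' exhaustively by total size, so the returned index is the true minimum.
#'
#' @param data A one-row data frame with `e1`, `n1`, `e0`, `n0`, or `NULL`
#'   if the four counts are given directly.
#' @param e1,n1,e0,n0 Counts, used when `data` is `NULL`.
#' @param method Per-study test: `"fisher"` (exact conditional) or
#'   `"chisq"` (Pearson, no Yates correction).
#' @param alpha Significance level.
#' @param cap Maximum total modification size (default `n1 + n0`).
#' @return A `fragility` object (`method = "study-exact"`).
#' @examples
#' fragility_study(e1 = 1, n1 = 20, e0 = 9, n0 = 20)
#' @export
fragility_study <- function(data = NULL, e1, n1, e0, n0,
                            method = c("fisher", "chisq"),
                            alpha = 0.05, cap = NULL) {
  method <- match.arg(method)
  if (!is.null(data)) {
    data <- one_ma(data)
    if (nrow(data) != 1L) {
      abort("`data` must contain exactly one study.",
            class = "metafrag_bad_data")
    }
    e1 <- data$e1; n1 <- data$n1; e0 <- data$e0; n0 <- data$n0
  }
  stopifnot(n1 > 0, n0 > 0, e1 >= 0, e0 >= 0, e1 <= n1, e0 <= n0)
  if (is.null(cap)) cap <- n1 + n0
  pfun <- function(a, c) {
    tab <- matrix(c(a, n1 - a, c, n0 - c), 2)
    if (method == "fisher") fisher.test(tab)$p.value
    else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  p0 <- pfun(e1, e0)
  sig0 <- p0 < alpha
  total_n <- n1 + n0
  spec <- list(measure = "2x2", test = method, alpha = alpha)
  for (m in seq_len(cap)) {
    for (d1 in (-m):m) {
      a <- e1 + d1
      if (a < 0 || a > n1) next
      r <- m - abs(d1)
      for (d0 in unique(c(-r, r))) {
        c0 <- e0 + d0
        if (c0 < 0 || c0 > n0) next
        p <- pfun(a, c0)
        if ((p < alpha) != sig0) {
          dat <- tibble::tibble(ma_id = "study", study_id = "study_1",
                                e1 = e1, n1 = n1, e0 = e0, n0 = n0)
          delta <- c(d1, d0)
          steps <- list()
          if (d1 != 0) for (j in seq_len(abs(d1))) {
            steps[[length(steps) + 1L]] <- c(1L, 1L, sign(d1))
          }
          if (d0 != 0) for (j in seq_len(abs(d0))) {
            steps[[length(steps) + 1L]] <- c(1L, 0L, sign(d0))
          }
          sm <- do.call(rbind, steps)
          plan <- tibble::tibble(step = seq_along(steps),
                                 study = 1L, study_id = "study_1",
                                 arm = as.integer(sm[, 2]),
                                 delta = as.integer(sm[, 3]),
                                 p_after = c(rep(NA_real_, m - 1L), p))
          return(new_fragility(m, attainable = TRUE,
                               direction = if (sig0) "toward_null" else "toward_significance",
                               plan = plan, trail = plan$p_after, p0 = p0,
                               sig0 = sig0, total_n = total_n, cap = cap,
                               method = "study-exact", spec = spec))
        }
      }
    }
  }
  new_fragility(NA, attainable = FALSE,
                direction = if (sig0) "toward_null" else "toward_significance",
                plan = empty_plan(), trail = double(), p0 = p0, sig0 = sig0,
                total_n = total_n, cap = cap, method = "study-exact",
                spec = spec)
}

#' Fragility quotient
#'
#' The fragility index divided by the total sample size of all included
#' studies: the proportion of enrolled patients whose event status would
#' need to change to alter the significance verdict.
#'
#' @param fi Fragility index (positive integer), or a `fragility` object.
#' @param total_n Total sample size across all included studies (ignored
#'   when `fi` is a `fragility` object).
#' @return The exact ratio `fi / total_n`; `NA` when the index is not
#'   attainable.
#' @examples
#' fragility_quotient(5, 1000)
#' @export
fragility_quotient <- function(fi, total_n = NULL) {
  if (inherits(fi, "fragility")) {
    return(fi$fq)
  }
  stopifnot(is.numeric(total_n), total_n > 0)
  if (any(!is.na(fi) & fi < 1)) {
    abort("The fragility index is at least 1 by definition.",
          class = "metafrag_bad_data")
  }
  fi / total_n
}

#' @export
print.fragility <- function(x, ...) {
  cat("<fragility> ", x$method, " search, ",
      if (!is.null(x$spec$scenario)) paste0(x$spec$scenario, "/", x$spec$measure)
      else paste0("single study (", x$spec$test, " test)"),
      ", initially ", x$initial_verdict, "\n", sep = "")
  if (x$attainable) {
    cat(sprintf("  FI = %d (%s), FQ = %.6g (total n = %d)\n",
                x$fi, x$direction, x$fq, x$total_n))
  } else {
    cat(sprintf("  not attainable within cap = %d modifications\n", x$cap))
  }
  invisible(x)
}
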