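#' Grid-search configuration for G-estimation
#'
#' The balance point is located by a coarse grid over the search box
#' followed by nested local refinements down to `fine_step`; the
#' refinement keeps the best few coarse candidates so that a locally
#' flat or mildly multimodal balance surface does not trap the search.
#'
#' @param lower,upper search bounds on each `psi` axis.
#' @param coarse_step increment of the first-pass grid.
#' @param fine_step terminal grid resolution.
#' @param refine_levels number of successive local refinement passes
#'   between `coarse_step` and `fine_step` (step sizes interpolate
#'   geometrically).
#' @param test balance-test flavour: `"score"` (cause-specific log-rank,
#'   the default) or `"wald"` (Wald statistic of the arm coefficient in
#'   a cause-specific Cox fit).  The two are asymptotically equivalent;
#'   the score form is far cheaper inside the grid search.
#' @param recensor apply re-censoring (both arms) inside the balance
#'   test, the default.  Re-censoring keeps the latent-scale censoring
#'   non-informative, which this generator's cause-linked time
#'   transformation otherwise violates badly.  `FALSE` compares raw
#'   latent times with the observed censoring status; provided for
#'   diagnostics only.
#' @param tie_tol chi-square tolerance within which balance statistics
#'   are treated as indistinguishable: among all evaluated points whose
#'   statistic lies within `tie_tol` of the minimum, the smallest-norm
#'   `psi` is returned (then lexicographic order).  Re-censoring drains
#'   information from the test at extreme negative `psi`, so on noisy
#'   or weakly identified surfaces the literal argmin can sit in a
#'   spuriously flat far region; preferring the least extreme of the
#'   statistically equivalent balance points removes that artifact.
#'   Set to 0 for the literal argmin.
#' @param keep_top number of candidate points carried into each
#'   refinement pass.
#' @return An object of class `"gsearch_config"`.
#' @export
gsearch_config <- function(lower = -3, upper = 3, coarse_step = 0.25,
                           fine_step = 0.001, refine_levels = 4,
                           test = c("score", "wald"), recensor = TRUE,
                           tie_tol = 0.5, keep_top = 3L) {
  test <- match.arg(test)
  stopifnot(lower <= upper, coarse_step > 0, fine_step > 0,
            fine_step <= coarse_step, refine_levels >= 1, keep_top >= 1,
            is.logical(recensor), tie_tol >= 0)
  structure(list(lower = lower, upper = upper, coarse_step = coarse_step,
                 fine_step = fine_step, refine_levels = as.integer(refine_levels),
                 test = test, recensor = recensor, tie_tol = tie_tol,
                 keep_top = as.integer(keep_top)),
            class = "gsearch_config")
}

# Two-sample log-rank (score) Z statistic, group coded 0/1; sign is that
# of the group-1 excess of observed over expected events.  Returns 0
# when no events or no variance (degenerate stratum), which keeps the
# balance surface finite at extreme psi.
logrank_z <- function(time, event, group) {
  ord <- order(time)
  t <- time[ord]; e <- event[ord]; g <- group[ord]
  n <- length(t)
  idx <- which(e)
  if (length(idx) == 0L) return(0)
  n1_at <- rev(cumsum(rev(g)))          # group-1 at risk by sorted position
  ft <- t[idx]; fg <- g[idx]
  first <- !duplicated(ft)
  uid <- cumsum(first)
  d <- tabulate(uid)                    # events at each distinct time
  d1 <- as.vector(rowsum(fg, uid))
  pos <- match(ft[first], t)            # first sorted position of each time
  N <- n - pos + 1
  N1 <- n1_at[pos]
  OE <- sum(d1 - d * N1 / N)
  V <- sum(d * (N1 / N) * (1 - N1 / N) * (N - d) / pmax(N - 1, 1))
  if (V <= 0) return(0)
  OE / sqrt(V)
}

# Wald Z of the arm coefficient in a cause-specific Cox fit; score-limit
# 0 when the fit is degenerate (no events, or events confined to an arm
# with infinite coefficient).
cox_wald_z <- function(time, event, group) {
  if (sum(event) == 0L) return(0)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ group),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ group))
    })
  if (is.null(fit)) return(0)
  z <- fit$coefficients[1L] / sqrt(fit$var[1L, 1L])
  if (!is.finite(z)) 0 else unname(z)
}

#' Randomization balance test at a candidate effect pair
#'
#' Computes the adjusted outcomes `(X, Delta)` of [adjusted_outcome()]
#' for every subject at `psi` (re-censoring applied in both arms, so
#' the censoring stays non-informative on the latent scale and the
#' comparison is randomization-valid) and tests whether the latent
#' lifetimes are balanced across randomized arms: one cause-specific
#' two-sample test per cause (the other cause treated as censoring),
#' combined as `statistic = Z1^2 + Z2^2` with a chi-square reference on
#' 2 df.  At the true `psi` the latent lifetimes are independent of the
#' arm, so the statistic is small and the p-value large.
#'
#' @param data subject data frame with both arms represented.
#' @param psi a [psi_pair()] or numeric vector `c(psi_E, psi_C)`.
#' @param test `"score"` (log-rank) or `"wald"`; see [gsearch_config()].
#' @param recensor re-censor inside the test; see [gsearch_config()].
#' @return A list of class `"g_test"` with elements `psi`, `statistic`,
#'   `p_value` and the per-cause `z` pair.
#' @export
balance_test <- function(data, psi, test = c("score", "wald"),
                         recensor = TRUE) {
  test <- match.arg(test)
  psi <- as_psi_pair(psi)
  check_balance_data(data)
  if (recensor) {
    ao <- adjusted_outcome(data, psi)
    time <- ao$X
    status <- ao$Delta
  } else {
    time <- latent_time(data, psi)
    status <- data$delta
  }
  zfun <- if (test == "score") logrank_z else cox_wald_z
  z1 <- zfun(time, status == 1L, data$G)
  z2 <- zfun(time, status == 2L, data$G)
  stat <- z1^2 + z2^2
  structure(list(psi = psi, statistic = stat,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 z = c(z1 = z1, z2 = z2)),
            class = "g_test")
}

check_balance_data <- function(data, causes = c(1L, 2L)) {
  if (length(unique(data$G)) < 2L)
    stop("both randomized arms must be present")
  for (k in causes)
    if (sum(data$delta == k) < 2L)
      stop("fewer than 2 events of cause ", k,
           " observed: balance test undefined")
  invisible(TRUE)
}

# Joint two-cause log-rank statistic Z1^2 + Z2^2 sharing a single sort:
# both cause-specific tests run on the same adjusted times, so the risk
# sets coincide and only the event labels differ.
logrank2_stat <- function(X, status, G) {
  ord <- order(X)
  x <- X[ord]; s <- status[ord]; g <- G[ord]
  n <- length(x)
  n1_at <- rev(cumsum(rev(g)))
  zsq <- function(k) {
    idx <- which(s == k)
    if (!length(idx)) return(0)
    ft <- x[idx]; fg <- g[idx]
    first <- !duplicated(ft)
    uid <- cumsum(first)
    d <- tabulate(uid)
    d1 <- as.vector(rowsum(fg, uid))
    pos <- match(ft[first], x)
    N <- n - pos + 1
    N1 <- n1_at[pos]
    OE <- sum(d1 - d * N1 / N)
    V <- sum(d * (N1 / N) * (1 - N1 / N) * (N - d) / pmax(N - 1, 1))
    if (V <= 0) 0 else OE^2 / V
  }
  zsq(1L) + zsq(2L)
}

# Evaluate the 2-D balance statistic on a matrix of psi pairs without
# re-validating the data each time.  Precomputes the per-subject
# decomposition once; each evaluation is a handful of vector ops plus
# one shared log-rank pass over both causes.
eval_surface <- function(data, psis, test, recensor = FALSE) {
  delta <- data$delta; C <- data$C; G <- data$G
  t_un <- data$t_unexposed
  tex1 <- data$t_exposed * (delta != 2L)  # exposure scaled by psi_E
  tex2 <- data$t_exposed * (delta == 2L)  # exposure scaled by psi_C
  is0 <- delta == 0L
  stats_out <- numeric(nrow(psis))
  for (i in seq_len(nrow(psis))) {
    pE <- psis[i, 1L]; pC <- psis[i, 2L]
    U <- t_un + exp(pE) * tex1 + exp(pC) * tex2
    if (recensor) {
      eE <- exp(min(pE, 0)); eC <- exp(min(pC, 0))
      bound <- C * c(min(eE, eC), eE, eC)[delta + 1L]
      X <- pmin(U, bound)
      X[is0] <- bound[is0]
      status <- delta * (U <= bound)
    } else {
      X <- U
      status <- delta
    }
    if (test == "score") {
      stats_out[i] <- logrank2_stat(X, status, G)
    } else {
      z1 <- cox_wald_z(X, status == 1L, G)
      z2 <- cox_wald_z(X, status == 2L, G)
      stats_out[i] <- z1^2 + z2^2
    }
  }
  stats_out
}

# Grid of psi values clipped to the search box, rounded to avoid
# floating-point drift between passes.
axis_grid <- function(center, half_width, step, lower, upper) {
  g <- seq(center - half_width, center + half_width, by = step)
  g <- round(g, 9)
  unique(pmin(pmax(g, lower), upper))
}

#' Two-dimensional G-estimate of the cause-specific effect pair
#'
#' Searches the box `[lower, upper]^2` for the `psi` pair at which the
#' randomization balance test is least significant (maximal p-value,
#' equivalently minimal statistic): a coarse grid locates candidate
#' basins, then nested local grids shrink the resolution geometrically
#' to `fine_step`.  Ties are broken toward the smallest Euclidean norm,
#' then lexicographically, so the result is deterministic.
#'
#' @param data subject data frame with both arms represented.
#' @param config a [gsearch_config()].
#' @return A list of class `"g_estimate"` with elements `psi_hat` (a
#'   [psi_pair()]), `statistic`, `p_value`, `boundary` (`TRUE` if the
#'   maximizer sits on the search boundary, suggesting
#'   non-identifiability), and `trace`, a data frame of every evaluated
#'   point (`psi_E`, `psi_C`, `statistic`, `level`).
#' @export
g_estimate <- function(data, config = gsearch_config()) {
  check_balance_data(data)
  lo <- config$lower; up <- config$upper
  steps <- search_schedule(config)
  ax <- axis_grid((lo + up) / 2, (up - lo) / 2, config$coarse_step, lo, up)
  psis <- as.matrix(expand.grid(psi_E = ax, psi_C = ax))
  stat <- eval_surface(data, psis, config$test, config$recensor)
  trace <- data.frame(psi_E = psis[, 1L], psi_C = psis[, 2L],
                      statistic = stat, level = 0L)
  prev_step <- config$coarse_step
  for (lev in seq_along(steps)) {
    s <- steps[lev]
    top <- unique(rbind(head_candidates(trace, config$keep_top),
                        select_best(trace, config$tie_tol)))
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(top)), function(j) {
      gE <- axis_grid(top$psi_E[j], 1.5 * prev_step, s, lo, up)
      gC <- axis_grid(top$psi_C[j], 1.5 * prev_step, s, lo, up)
      as.matrix(expand.grid(psi_E = gE, psi_C = gC))
    })))
    new <- !duplicated(rbind(as.matrix(trace[, 1:2]), cand))[-seq_len(nrow(trace))]
    cand <- cand[new, , drop = FALSE]
    if (nrow(cand)) {
      stat <- eval_surface(data, cand, config$test, config$recensor)
      trace <- rbind(trace, data.frame(psi_E = cand[, 1L], psi_C = cand[, 2L],
                                       statistic = stat, level = lev))
    }
    prev_step <- s
  }
  anchor <- select_best(trace, config$tie_tol)
  local <- trace[abs(trace$psi_E - anchor$psi_E) <= 2 * config$coarse_step &
                   abs(trace$psi_C - anchor$psi_C) <= 2 * config$coarse_step, ,
                 drop = FALSE]
  best <- head_candidates(local, 1L)
  psi_hat <- psi_pair(best$psi_E, best$psi_C)
  boundary <- any(abs(c(best$psi_E, best$psi_C) - lo) < 1e-9) ||
    any(abs(c(best$psi_E, best$psi_C) - up) < 1e-9)
  if (boundary)
    warning("G-estimate lies on the search boundary; ",
            "the effect pair may not be identified on this dataset")
  structure(list(psi_hat = psi_hat, statistic = best$statistic,
                 p_value = stats::pchisq(best$statistic, 2, lower.tail = FALSE),
                 boundary = boundary, trace = trace),
            class = "g_estimate")
}

# Geometric step schedule from coarse_step down to fine_step.
search_schedule <- function(config) {
  k <- config$refine_levels
  s <- exp(seq(log(config$coarse_step), log(config$fine_step),
               length.out = k + 1L))[-1L]
  s[length(s)] <- config$fine_step
  s
}

# Best rows of a trace under the deterministic tie-break:
# statistic, then Euclidean norm of psi, then lexicographic order.
head_candidates <- function(trace, k) {
  o <- order(trace$statistic,
             trace$psi_E^2 + trace$psi_C^2,
             trace$psi_E, trace$psi_C)
  trace[o[seq_len(min(k, nrow(trace)))], , drop = FALSE]
}

# Near-tie anchor: among all points statistically indistinguishable
# from the minimum (within tie_tol on the chi-square scale), the
# smallest-norm psi, then lexicographic.  Used to pick the least
# extreme basin; the final estimate is the local argmin around it.
select_best <- function(trace, tie_tol) {
  near <- trace[trace$statistic <= min(trace$statistic) + tie_tol, ,
                drop = FALSE]
  o <- order(near$psi_E^2 + near$psi_C^2, near$statistic,
             near$psi_E, near$psi_C)
  near[o[1L], , drop = FALSE]
}

# One-dimensional analogue of select_best; returns the anchor psi.
select_best1 <- function(trace, tie_tol) {
  near <- trace[trace$statistic <= min(trace$statistic) + tie_tol, ,
                drop = FALSE]
  o <- order(abs(near$psi), near$statistic, near$psi)
  near$psi[o[1L]]
}

#' One-dimensional G-estimate on the composite endpoint
#'
#' Collapses both causes into a single event and estimates the common
#' log-AFT effect `psi`: latent times are
#' `U = exp(psi) * t_exposed + t_unexposed`, re-censoring uses
#' `C * exp(min(psi, 0))`, and the balance statistic is the single
#' two-sample test `Z^2` (chi-square, 1 df).  This is the classical
#' single-event RPSFT G-estimation used by the composite-endpoint
#' comparators.
#'
#' @param data subject data frame (`delta` may still carry causes 1 and
#'   2; both count as the composite event).
#' @param config a [gsearch_config()].
#' @return A list of class `"g_estimate"` with scalar `psi_hat`.
#' @export
g_estimate_composite <- function(data, config = gsearch_config()) {
  if (length(unique(data$G)) < 2L)
    stop("both randomized arms must be present")
  if (sum(data$delta != 0L) < 2L)
    stop("fewer than 2 composite events: balance test undefined")
  lo <- config$lower; up <- config$upper
  zfun <- if (config$test == "score") logrank_z else cox_wald_z
  ev <- data$delta != 0L
  eval1 <- function(psi) {
    vapply(psi, function(p) {
      U <- exp(p) * data$t_exposed + data$t_unexposed
      if (config$recensor) {
        bound <- data$C * exp(min(p, 0))
        X <- ifelse(ev, pmin(U, bound), bound)
        keep <- ev & U <= bound
      } else {
        X <- U
        keep <- ev
      }
      zfun(X, keep, data$G)^2
    }, numeric(1))
  }
  ax <- axis_grid((lo + up) / 2, (up - lo) / 2, config$coarse_step, lo, up)
  trace <- data.frame(psi = ax, statistic = eval1(ax), level = 0L)
  prev_step <- config$coarse_step
  for (lev in seq_along(search_schedule(config))) {
    s <- search_schedule(config)[lev]
    o <- order(trace$statistic, abs(trace$psi), trace$psi)
    top <- trace$psi[o[seq_len(min(config$keep_top, nrow(trace)))]]
    top <- unique(c(top, select_best1(trace, config$tie_tol)))
    cand <- unique(unlist(lapply(top, axis_grid,
                                 half_width = 1.5 * prev_step, step = s,
                                 lower = lo, upper = up)))
    cand <- setdiff(cand, trace$psi)
    if (length(cand))
      trace <- rbind(trace, data.frame(psi = cand, statistic = eval1(cand),
                                       level = lev))
    prev_step <- s
  }
  anchor <- select_best1(trace, config$tie_tol)
  local <- trace[abs(trace$psi - anchor) <= 2 * config$coarse_step, ]
  o <- order(local$statistic, abs(local$psi), local$psi)
  best <- local[o[1L], ]
  boundary <- abs(best$psi - lo) < 1e-9 || abs(best$psi - up) < 1e-9
  if (boundary)
    warning("composite G-estimate lies on the search boundary")
  structure(list(psi_hat = best$psi, statistic = best$statistic,
                 p_value = stats::pchisq(best$statistic, 1, lower.tail = FALSE),
                 boundary = boundary, trace = trace),
            class = "g_estimate")
}
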