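#' Convert a log-AFT effect to a hazard ratio
#'
#' Under a Weibull lifetime with shape `gamma`, the AFT effect and the
#' hazard ratio are linked by `psi = log(HR) / gamma`; for exponential
#' lifetimes (`gamma = 1`) `hr = exp(psi)` and the multiplicative
#' lifetime extension attributable to treatment is `exp(-psi)`.
#'
#' @param psi log-AFT effect (scalar or vector).
#' @param gamma shape parameter, positive.
#' @return Hazard ratio(s) `exp(psi * gamma)`.
#' @export
psi_to_hr <- function(psi, gamma = 1) {
  stopifnot(gamma > 0)
  exp(psi * gamma)
}

#' @rdname psi_to_hr
#' @param hr hazard ratio(s), positive.
#' @export
hr_to_psi <- function(hr, gamma = 1) {
  stopifnot(gamma > 0, all(hr > 0))
  log(hr) / gamma
}

# Cox PH fit of the arm indicator for one endpoint; Wald HR and 95% CI
# on the log scale.
fit_hr <- function(time, event, G) {
  if (sum(event) == 0L)
    stop("no events for this endpoint: hazard ratio undefined")
  fit <- survival::coxph(survival::Surv(time, event) ~ G)
  b <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  list(hr = exp(b), ci_lower = exp(b - 1.96 * se),
       ci_upper = exp(b + 1.96 * se), se = se)
}

# Assemble one method's estimate from an analysis dataset.
make_estimate <- function(method, time, status, G, psi_hat = NULL,
                          composite = FALSE) {
  f1 <- fit_hr(time, status == 1L, G)
  est <- list(method = method,
              hr = f1$hr, ci_lower = f1$ci_lower, ci_upper = f1$ci_upper,
              hr_competing = NA_real_,
              censor_frac = mean(status == 0L),
              psi_hat = psi_hat)
  if (!composite) {
    f2 <- tryCatch(fit_hr(time, status == 2L, G), error = function(e) NULL)
    if (!is.null(f2)) est$hr_competing <- f2$hr
  }
  structure(est, class = "method_estimate")
}

#' @export
print.method_estimate <- function(x, ...) {
  cat(sprintf("%s: HR = %.3f (95%% CI %.3f-%.3f), %.1f%% censored\n",
              x$method, x$hr, x$ci_lower, x$ci_upper, 100 * x$censor_frac))
  if (!is.na(x$hr_competing))
    cat(sprintf("  competing-event HR = %.3f\n", x$hr_competing))
  if (!is.null(x$psi_hat))
    cat("  psi_hat =", paste(sprintf("%.3f", x$psi_hat), collapse = ", "), "\n")
  invisible(x)
}

#' Intention-to-treat cause-specific estimate
#'
#' Fits cause-specific Cox models of the randomized arm on the observed
#' data, ignoring switching: cause 1 as endpoint with cause 2 treated as
#' censoring (and symmetrically for the competing-event hazard ratio).
#'
#' @param data subject data frame.
#' @return A `"method_estimate"`: `hr` (cause-1 cause-specific HR with
#'   95% Wald CI), `hr_competing`, `censor_frac`.
#' @export
estimate_itt <- function(data) {
  stopifnot(length(unique(data$G)) == 2L)
  make_estimate("ITT", data$T, data$delta, data$G)
}

#' Per-protocol (censor-at-switch) cause-specific estimate
#'
#' Replaces every switcher's observation by a censoring at the switch
#' time, then proceeds as [estimate_itt()].  Because switching follows
#' progression, this censoring is informative and the comparison is
#' biased — the estimator is included as a naive comparator.
#'
#' @param data subject data frame.
#' @return A `"method_estimate"` with method `"PP-cen"`.
#' @export
estimate_ppcen <- function(data) {
  stopifnot(length(unique(data$G)) == 2L)
  d <- data
  sw <- !is.na(d$W)
  d$T[sw] <- d$W[sw]
  d$delta[sw] <- 0L
  make_estimate("PP-cen", d$T, d$delta, d$G)
}

#' RPSFT cause-specific estimate with two-dimensional G-estimation
#'
#' Estimates the structural effect pair by [g_estimate()], then fits
#' cause-specific Cox models on the switching-adjusted dataset: the
#' experimental arm keeps its observed `(T, delta)`, while every
#' control-arm subject is replaced by the adjusted
#' `(X(psi_hat), Delta(psi_hat))` — latent time with re-censoring
#' applied in the control arm only.  The confidence interval is the
#' naive Wald interval of the final fit and does not propagate the
#' uncertainty in `psi_hat`, so its coverage is expected to fall
#' somewhat below nominal.
#'
#' @param data subject data frame.
#' @param gconfig a [gsearch_config()].
#' @return A `"method_estimate"` with method `"RPSFT"` and the fitted
#'   `psi_hat` pair attached.
#' @export
estimate_rpsft <- function(data, gconfig = gsearch_config()) {
  g <- g_estimate(data, gconfig)
  ao <- adjusted_outcome(data, g$psi_hat)
  ctrl <- data$G == 0L
  time <- ifelse(ctrl, ao$X, data$T)
  status <- ifelse(ctrl, ao$Delta, data$delta)
  est <- make_estimate("RPSFT", time, as.integer(status), data$G,
                       psi_hat = g$psi_hat)
  est$boundary <- g$boundary
  est
}

#' Composite-endpoint comparators (ITT-com, PPcen-com, RPSFT-com)
#'
#' Maps both causes to a single composite event and runs the three
#' estimators on the collapsed data; RPSFT-com uses the one-dimensional
#' G-estimate of [g_estimate_composite()].  No competing-event hazard
#' ratio is defined for these methods.
#'
#' @param data subject data frame.
#' @param gconfig a [gsearch_config()] for RPSFT-com.
#' @return A named list of three `"method_estimate"` objects:
#'   `"ITT-com"`, `"PPcen-com"`, `"RPSFT-com"`.
#' @export
estimate_composite_family <- function(data, gconfig = gsearch_config()) {
  d <- data
  d$delta <- ifelse(d$delta != 0L, 1L, 0L)

  itt <- make_estimate("ITT-com", d$T, d$delta, d$G, composite = TRUE)

  dp <- d
  sw <- !is.na(dp$W)
  dp$T[sw] <- dp$W[sw]
  dp$delta[sw] <- 0L
  pp <- make_estimate("PPcen-com", dp$T, dp$delta, dp$G, composite = TRUE)

  g <- g_estimate_composite(d, gconfig)
  U <- exp(g$psi_hat) * d$t_exposed + d$t_unexposed
  bound <- d$C * exp(min(g$psi_hat, 0))
  ctrl <- d$G == 0L
  ev <- d$delta != 0L
  X <- ifelse(ev, pmin(U, bound), bound)
  Delta <- ifelse(ev & U <= bound, 1L, 0L)
  time <- ifelse(ctrl, X, d$T)
  status <- ifelse(ctrl, Delta, d$delta)
  rp <- make_estimate("RPSFT-com", time, as.integer(status), d$G,
                      psi_hat = g$psi_hat, composite = TRUE)
  rp$boundary <- g$boundary

  list("ITT-com" = itt, "PPcen-com" = pp, "RPSFT-com" = rp)
}
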