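#' Monte Carlo performance summary for one method
#'
#' Aggregates per-replication hazard-ratio estimates into the usual
#' replication-study measures: mean and empirical SD of the estimated
#' HR, mean squared error about the true HR, absolute relative bias in
#' percent, coverage of the nominal 95% interval, and the mean
#' censoring fraction of the analysis datasets.
#'
#' The MSE is taken about the true value, so up to the `(n-1)/n`
#' variance convention it decomposes as `mse = sd^2 + (mean - true)^2`.
#'
#' @param estimates data frame with one row per replication and columns
#'   `hr`, `ci_lower`, `ci_upper`, `censor_frac`.
#' @param true_hr the true hazard ratio of the target endpoint.
#' @param method optional method label carried into the output.
#' @return A one-row data frame of class `"scenario_summary"` with
#'   columns `method`, `n_reps`, `mean_hr`, `sd_hr`, `mse`,
#'   `rel_bias_pct`, `coverage`, `censor_frac`.
#' @export
summarize_estimates <- function(estimates, true_hr, method = NA_character_) {
  stopifnot(nrow(estimates) >= 2L, true_hr > 0)
  hr <- estimates$hr
  mean_hr <- mean(hr)
  out <- data.frame(
    method = method,
    n_reps = nrow(estimates),
    mean_hr = mean_hr,
    sd_hr = stats::sd(hr),
    mse = mean((hr - true_hr)^2),
    rel_bias_pct = abs(mean_hr - true_hr) / true_hr * 100,
    coverage = mean(estimates$ci_lower <= true_hr &
                      true_hr <= estimates$ci_upper),
    censor_frac = mean(estimates$censor_frac))
  class(out) <- c("scenario_summary", "data.frame")
  out
}
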