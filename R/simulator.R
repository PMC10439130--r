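#' Scenario configuration for a two-arm competing-risks trial
#'
#' Bundles the design parameters of one simulated randomized trial:
#' true cause-specific hazard ratios, sample size, switching fraction,
#' follow-up design and the distribution of the progression fraction.
#'
#' Subjects enter uniformly on `[0, entry_max]` (calendar months) and are
#' administratively censored at the fixed end of study `eos`, so the
#' per-subject censoring time on the study clock is `C = eos - entry`.
#' Control-arm subjects progress at a `Beta(beta_alpha, beta_beta)`
#' fraction of their latent lifetime and may switch to the experimental
#' treatment at that moment; a switcher's residual lifetime is stretched
#' by the AFT factor `exp(-psi)` with `psi = log(HR) / gamma`
#' (`gamma = 1` corresponds to exponential lifetimes).
#'
#' @param hr_E true cause-1 (event of interest) hazard ratio,
#'   experimental vs control.
#' @param hr_C true cause-2 (competing event) hazard ratio.
#' @param n_per_arm subjects per randomized arm.
#' @param switch_pct probability that a control subject switches at
#'   progression, in `[0, 1]`.
#' @param eos end-of-study calendar time (months).
#' @param entry_max upper bound of the uniform entry window (months).
#' @param beta_alpha,beta_beta shape parameters of the Beta distribution
#'   of the progression fraction.
#' @param gamma AFT shape parameter used in the `psi = log(HR)/gamma`
#'   conversion; 1 for exponential lifetimes.
#' @param n_reps default number of Monte Carlo replications.
#' @param seed default root RNG seed for [run_scenario()].
#' @return An object of class `"scenario_config"` (a named list).
#' @seealso [simulate_trial()], [calibrate_hazards()], [run_scenario()]
#' @export
scenario_config <- function(hr_E = 0.5, hr_C = 1, n_per_arm = 250,
                            switch_pct = 0.3, eos = 90, entry_max = 20,
                            beta_alpha = 2, beta_beta = 2, gamma = 1,
                            n_reps = 1000, seed = 1L) {
  stopifnot(hr_E > 0, hr_C > 0, n_per_arm >= 1,
            switch_pct >= 0, switch_pct <= 1,
            entry_max > 0, eos > entry_max,
            beta_alpha > 0, beta_beta > 0, gamma > 0, n_reps >= 1)
  structure(list(hr_E = hr_E, hr_C = hr_C, n_per_arm = as.integer(n_per_arm),
                 switch_pct = switch_pct, eos = eos, entry_max = entry_max,
                 beta_alpha = beta_alpha, beta_beta = beta_beta,
                 gamma = gamma, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Trial scenario: HR_E =", x$hr_E, ", HR_C =", x$hr_C,
      ",", x$n_per_arm, "per arm\n")
  cat("  switching:", sprintf("%.0f%%", 100 * x$switch_pct),
      "at progression ~ Beta(", x$beta_alpha, ",", x$beta_beta, ") fraction\n")
  cat("  follow-up: entry ~ U(0,", x$entry_max, "), end of study at",
      x$eos, "months\n")
  invisible(x)
}

#' Construct a set of cause-specific hazards
#'
#' @param h_s1,h_s2 control-arm hazards (events/month) for cause 1
#'   (event of interest) and cause 2 (competing event).
#' @param h_m1,h_m2 experimental-arm hazards.
#' @return An object of class `"hazard_set"`.
#' @export
hazard_set <- function(h_s1, h_s2, h_m1, h_m2) {
  stopifnot(h_s1 > 0, h_s2 > 0, h_m1 > 0, h_m2 > 0)
  structure(list(h_s1 = h_s1, h_s2 = h_s2, h_m1 = h_m1, h_m2 = h_m2),
            class = "hazard_set")
}

# Probability that an exponential(h) lifetime falls before an
# administrative censoring time C ~ U(a, b):
# P(T <= C) = 1 - E[exp(-h C)] = 1 - (exp(-h a) - exp(-h b)) / (h (b - a)).
p_event_unif <- function(h, a, b) {
  1 - (exp(-h * a) - exp(-h * b)) / (h * (b - a))
}

#' Calibrate cause-specific hazards to target event fractions
#'
#' Solves for constant control-arm cause-specific hazards `(h_s1, h_s2)`
#' such that, in a control arm with no switching under the configured
#' entry/censoring design, the expected fraction of subjects observed to
#' fail from cause 1 is `target_p1` and from cause 2 is `target_p2`.
#'
#' With total hazard `h = h_s1 + h_s2` and censoring time
#' `C ~ U(eos - entry_max, eos)`, the expected fraction with any
#' observed event is `P(any) = 1 - E[exp(-h C)]` (closed form), and
#' cause k takes the share `h_sk / h` of it.  The total hazard is found
#' by a root search on `P(any) = target_p1 + target_p2` and split in the
#' ratio `target_p1 : target_p2`.  Experimental-arm hazards are the
#' control hazards multiplied by the configured hazard ratios.
#'
#' @param target_p1,target_p2 target observed event fractions for the
#'   two causes; both strictly positive with sum in (0, 1).
#' @param config a [scenario_config()]; only `eos`, `entry_max`, `hr_E`
#'   and `hr_C` are used.
#' @return A [hazard_set()].
#' @export
calibrate_hazards <- function(target_p1 = 0.5, target_p2 = 0.2,
                              config = scenario_config()) {
  if (target_p1 <= 0 || target_p2 <= 0)
    stop("both target event fractions must be strictly positive ",
         "(a zero cause-specific hazard is degenerate)")
  p_tot <- target_p1 + target_p2
  if (p_tot >= 1)
    stop("target event fractions must sum to less than 1")
  a <- config$eos - config$entry_max
  b <- config$eos
  f <- function(h) p_event_unif(h, a, b) - p_tot
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 10
  if (f(upper) < 0)
    stop("no hazard attains the requested total event fraction ",
         "under this entry/censoring design")
  h <- stats::uniroot(f, lower = 1e-12, upper = upper, tol = 1e-12)$root
  h_s1 <- h * target_p1 / p_tot
  h_s2 <- h * target_p2 / p_tot
  hazard_set(h_s1, h_s2, h_s1 * config$hr_E, h_s2 * config$hr_C)
}

#' Draw latent failure times and causes
#'
#' Generates latent (uncensored) lifetimes under constant cause-specific
#' hazards: the all-cause time is exponential with rate `h_z1 + h_z2`
#' and, independently, the cause is 1 with probability
#' `h_z1 / (h_z1 + h_z2)`.
#'
#' @param hazards a [hazard_set()].
#' @param arm 0 for control, 1 for experimental.
#' @param n number of draws.
#' @return A data frame with columns `time` (months) and `cause` (1 or 2).
#' @export
draw_failure <- function(hazards, arm, n = 1) {
  stopifnot(arm %in% c(0, 1), n >= 1)
  h1 <- if (arm == 1) hazards$h_m1 else hazards$h_s1
  h2 <- if (arm == 1) hazards$h_m2 else hazards$h_s2
  time <- stats::rexp(n, rate = h1 + h2)
  cause <- ifelse(stats::rbinom(n, 1L, h1 / (h1 + h2)) == 1L, 1L, 2L)
  data.frame(time = time, cause = cause)
}

#' Apply progression-triggered switching to control-arm lifetimes
#'
#' For each control-arm subject, a progression fraction
#' `b ~ Beta(beta_alpha, beta_beta)` places progression (and candidate
#' switch) at `W = b * latent_time`.  The subject switches with
#' probability `switch_pct`; a switcher's total lifetime becomes
#' `T = W + exp(-psi_cause) * (latent_time - W)`, where `psi_cause` is
#' the cause-specific log-AFT effect (`psi_E` for cause 1, `psi_C` for
#' cause 2).  Non-switchers keep their latent lifetime and `W = NA`.
#'
#' Censoring is not applied here; [simulate_trial()] truncates these
#' lifetimes at the administrative censoring time afterwards.
#'
#' @param latent_time vector of latent control lifetimes (months).
#' @param cause parallel vector of causes (1 or 2).
#' @param config a [scenario_config()].
#' @param psi_E,psi_C log-AFT effects used to stretch a switcher's
#'   residual lifetime by `exp(-psi)`.
#' @return Data frame with columns `T` (total lifetime), `W` (switch
#'   time, `NA` for non-switchers), `t_unexposed`, `t_exposed`.
#' @export
apply_switching <- function(latent_time, cause, config, psi_E, psi_C) {
  stopifnot(all(latent_time > 0), all(cause %in% c(1L, 2L)))
  n <- length(latent_time)
  b <- stats::rbeta(n, config$beta_alpha, config$beta_beta)
  W <- b * latent_time
  sw <- stats::runif(n) < config$switch_pct
  psi <- ifelse(cause == 1L, psi_E, psi_C)
  T_out <- latent_time
  adj <- sw & psi != 0  # a null effect is the exact identity
  T_out[adj] <- W[adj] + exp(-psi[adj]) * (latent_time[adj] - W[adj])
  W[!sw] <- NA_real_
  data.frame(T = T_out, W = W,
             t_unexposed = ifelse(sw, W, T_out),
             t_exposed = ifelse(sw, T_out - W, 0))
}

#' Simulate one randomized trial with switching and competing risks
#'
#' Generates `n_per_arm` subjects per arm with staggered uniform entry,
#' exponential cause-specific failure times, administrative censoring at
#' the end of study, and progression-triggered control-to-experimental
#' switching whose lifetime extension follows the structural AFT model.
#'
#' A control subject whose candidate switch time falls at or beyond the
#' censoring time never actually switches and is recorded censored as a
#' non-switcher.  All times in the output are measured from
#' randomization; `entry` only determines the censoring time
#' `C = eos - entry`.
#'
#' @param config a [scenario_config()].
#' @param hazards a [hazard_set()]; by default hazards calibrated so
#'   that a control arm without switching under the config's own
#'   entry/censoring design yields about 50% cause-1 and 20% cause-2
#'   events (see [calibrate_hazards()]).
#' @return A data frame with one row per subject and columns `id`, `G`
#'   (0 control / 1 experimental), `entry`, `C`, `T`, `delta`
#'   (0 censored, 1 event of interest, 2 competing event), `W` (switch
#'   time, `NA` if never switched), `t_unexposed`, `t_exposed`.
#' @export
simulate_trial <- function(config, hazards = NULL) {
  if (is.null(hazards))
    hazards <- calibrate_hazards(0.5, 0.2, config)
  n <- config$n_per_arm
  psi_E <- hr_to_psi(config$hr_E, config$gamma)
  psi_C <- hr_to_psi(config$hr_C, config$gamma)

  entry <- stats::runif(2L * n, 0, config$entry_max)
  C <- config$eos - entry
  G <- rep(c(0L, 1L), each = n)

  ## experimental arm: fully exposed from randomization
  fe <- draw_failure(hazards, 1L, n)
  Ce <- C[G == 1L]
  Te <- pmin(fe$time, Ce)
  de <- ifelse(fe$time <= Ce, fe$cause, 0L)

  ## control arm: latent failure, then switching, then censoring
  fs <- draw_failure(hazards, 0L, n)
  Cs <- C[G == 0L]
  sw <- apply_switching(fs$time, fs$cause, config, psi_E, psi_C)
  is_sw <- !is.na(sw$W)
  late_sw <- is_sw & sw$W >= Cs  # would switch only after censoring
  Ts <- pmin(sw$T, Cs)
  ds <- ifelse(sw$T <= Cs, fs$cause, 0L)
  Ws <- sw$W
  Ws[late_sw] <- NA_real_
  t_un <- ifelse(is_sw & !late_sw, Ws, Ts)
  t_ex <- ifelse(is_sw & !late_sw, Ts - Ws, 0)
  t_un[late_sw] <- Cs[late_sw]

  out <- data.frame(
    id = seq_len(2L * n),
    G = G,
    entry = entry,
    C = C,
    T = c(Ts, Te),
    delta = as.integer(c(ds, de)),
    W = c(Ws, rep(NA_real_, n)),
    t_unexposed = c(t_un, rep(0, n)),
    t_exposed = c(t_ex, Te))
  out$T <- pmin(out$T, out$C)  # guard against FP drift at the boundary
  out
}
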