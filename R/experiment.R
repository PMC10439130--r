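#' The 18-scenario study grid
#'
#' Cross product of the competing-event hazard ratio (1, 2, 0.6), the
#' switching percentage (30, 60, 90%) and the end-of-study time (30, 90
#' months), with the event-of-interest hazard ratio fixed at 0.5 and
#' 250 subjects per arm.
#'
#' @param n_per_arm subjects per arm.
#' @param n_reps replications per scenario.
#' @return A data frame with 18 rows and columns `scenario`, `hr_E`,
#'   `hr_C`, `switch_pct`, `eos`, `n_per_arm`, `n_reps`.
#' @export
study_grid <- function(n_per_arm = 250, n_reps = 1000) {
  g <- expand.grid(hr_C = c(1, 2, 0.6), switch_pct = c(0.3, 0.6, 0.9),
                   eos = c(30, 90), KEEP.OUT.ATTRS = FALSE)
  data.frame(scenario = seq_len(nrow(g)), hr_E = 0.5, g,
             n_per_arm = n_per_arm, n_reps = n_reps)
}

all_methods <- c("ITT", "PP-cen", "RPSFT", "ITT-com", "PPcen-com", "RPSFT-com")

# Deterministic per-replication child seeds from one root seed, so any
# single replication can be reproduced in isolation:
# set.seed(root); seeds <- sample.int(.Machine$integer.max - 1, n_reps).
replication_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

# Run the requested estimators on one dataset; errors are captured per
# method so a degenerate replication does not abort the scenario.
run_estimators <- function(dat, methods, gconfig) {
  out <- list()
  grab <- function(name, expr) {
    e <- tryCatch(suppressWarnings(expr), error = function(err) err)
    out[[name]] <<- e
  }
  if ("ITT" %in% methods) grab("ITT", estimate_itt(dat))
  if ("PP-cen" %in% methods) grab("PP-cen", estimate_ppcen(dat))
  if ("RPSFT" %in% methods) grab("RPSFT", estimate_rpsft(dat, gconfig))
  if (any(c("ITT-com", "PPcen-com", "RPSFT-com") %in% methods)) {
    fam <- tryCatch(suppressWarnings(estimate_composite_family(dat, gconfig)),
                    error = function(err) err)
    for (m in intersect(c("ITT-com", "PPcen-com", "RPSFT-com"), methods))
      out[[m]] <- if (inherits(fam, "error")) fam else fam[[m]]
  }
  out
}

#' Run one Monte Carlo scenario
#'
#' Simulates `n_reps` trials under `config`, applies the requested
#' estimators to each, and aggregates the per-replication estimates
#' into one performance summary per method.  All methods are judged
#' against the true event-of-interest hazard ratio `config$hr_E`.
#' Replications where an estimator fails are excluded from that
#' method's summary and counted; a method with more than 5% failures is
#' flagged.
#'
#' @param config a [scenario_config()].
#' @param methods subset of
#'   `c("ITT", "PP-cen", "RPSFT", "ITT-com", "PPcen-com", "RPSFT-com")`.
#' @param n_reps,seed override the config's replication count and root
#'   seed.
#' @param gconfig a [gsearch_config()] for the RPSFT methods.
#' @param hazards optional [hazard_set()]; defaults to calibration
#'   under the config's own design (see [simulate_trial()]).
#' @param verbose print progress every 50 replications.
#' @return A list with `summary` (one row per method, see
#'   [summarize_estimates()], plus `n_failed` and `flagged`),
#'   `estimates` (long per-replication data frame), `hazards`,
#'   `config`, `seed`.
#' @export
run_scenario <- function(config, methods = all_methods,
                         n_reps = config$n_reps, seed = config$seed,
                         gconfig = gsearch_config(), hazards = NULL,
                         verbose = FALSE) {
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  if (is.null(hazards))
    hazards <- calibrate_hazards(0.5, 0.2, config)
  seeds <- replication_seeds(seed, n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    dat <- simulate_trial(config, hazards)
    ests <- run_estimators(dat, methods, gconfig)
    rows[[r]] <- do.call(rbind, lapply(names(ests), function(m) {
      e <- ests[[m]]
      if (inherits(e, "error"))
        data.frame(rep = r, method = m, hr = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, hr_competing = NA_real_,
                   censor_frac = NA_real_, error = conditionMessage(e))
      else
        data.frame(rep = r, method = m, hr = e$hr, ci_lower = e$ci_lower,
                   ci_upper = e$ci_upper, hr_competing = e$hr_competing,
                   censor_frac = e$censor_frac, error = NA_character_)
    }))
    if (verbose && r %% 50 == 0)
      message("  replication ", r, "/", n_reps)
  }
  estimates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(methods, function(m) {
    em <- estimates[estimates$method == m & !is.na(estimates$hr), ]
    n_failed <- n_reps - nrow(em)
    if (nrow(em) < 2L) {
      s <- data.frame(method = m, n_reps = nrow(em), mean_hr = NA_real_,
                      sd_hr = NA_real_, mse = NA_real_,
                      rel_bias_pct = NA_real_, coverage = NA_real_,
                      censor_frac = NA_real_)
    } else {
      s <- summarize_estimates(em, true_hr = config$hr_E, method = m)
    }
    s$n_failed <- n_failed
    s$flagged <- n_failed > 0.05 * n_reps
    s
  }))
  rownames(summary) <- NULL
  list(summary = summary, estimates = estimates, hazards = hazards,
       config = config, seed = seed)
}

#' Run the full (or partial) scenario grid
#'
#' @param grid a data frame as from [study_grid()]; rows may be
#'   subset or modified.
#' @param methods methods to run (see [run_scenario()]).
#' @param n_reps replications per scenario (overrides the grid column).
#' @param seed root seed; scenario `s` uses `seed + s` as its root.
#' @param gconfig a [gsearch_config()].
#' @param out_dir optional directory; per-scenario summary and
#'   replication CSVs plus a run-metadata JSON are written there.
#' @param verbose print progress.
#' @return A list with `summary` (stacked per-scenario summaries keyed
#'   by the grid columns) and `results` (per-scenario [run_scenario()]
#'   outputs).
#' @export
run_grid <- function(grid = study_grid(), methods = all_methods,
                     n_reps = NULL, seed = 1L, gconfig = gsearch_config(),
                     out_dir = NULL, verbose = TRUE) {
  results <- vector("list", nrow(grid))
  summaries <- vector("list", nrow(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- scenario_config(hr_E = g$hr_E, hr_C = g$hr_C,
                           n_per_arm = g$n_per_arm,
                           switch_pct = g$switch_pct, eos = g$eos,
                           n_reps = if (is.null(n_reps)) g$n_reps else n_reps,
                           seed = seed + g$scenario)
    if (verbose)
      message("scenario ", g$scenario, ": HR_C = ", g$hr_C, ", ",
              100 * g$switch_pct, "% switching, eos = ", g$eos)
    res <- run_scenario(cfg, methods = methods, gconfig = gconfig)
    s <- cbind(g[rep(1L, nrow(res$summary)), , drop = FALSE], res$summary,
               row.names = NULL)
    results[[i]] <- res
    summaries[[i]] <- s
    if (!is.null(out_dir)) {
      utils::write.csv(s, file.path(out_dir,
                                    sprintf("scenario-%02d-summary.csv",
                                            g$scenario)), row.names = FALSE)
      utils::write.csv(res$estimates,
                       file.path(out_dir,
                                 sprintf("scenario-%02d-replications.csv",
                                         g$scenario)), row.names = FALSE)
    }
  }
  summary <- do.call(rbind, summaries)
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "grid-summary.csv"),
                     row.names = FALSE)
    meta <- list(seed = seed, methods = methods,
                 n_reps = if (is.null(n_reps)) grid$n_reps else n_reps,
                 gsearch = unclass(gconfig),
                 r_version = R.version.string,
                 package_version = as.character(utils::packageVersion("rpsftcr")))
    jsonlite::write_json(meta, file.path(out_dir, "run-metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(summary = summary, results = results)
}

#' Panitumumab-like case-study demonstration (synthetic)
#'
#' Generates one synthetic dataset loosely emulating a colorectal
#' cancer trial of best supportive care with or without an EGFR
#' antibody, in which 75% of control patients crossed over at disease
#' progression, and runs all six estimators on it.  Endpoints: death
#' following disease progression (cause 1) and death without
#' progression (cause 2).
#'
#' The published trial is not available, so this is an illustrative
#' demo, not a validation: progression and death times are exponential
#' with medians 53 and 190 days, a switcher's residual survival has
#' median 49 days, control patients switch at progression with
#' probability `167/201` (the crossover fraction among progressors),
#' and the experimental-arm death hazard is scaled by `hr_exp`, a
#' choice the real generation does not pin down.  Follow-up is
#' administrative: entry uniform over one year, end of study at
#' `eos` days.
#'
#' @param seed RNG seed.
#' @param n_control,n_experimental arm sizes.
#' @param switch_prob probability of switching at progression for
#'   control progressors.
#' @param hr_exp illustrative all-cause hazard ratio applied to the
#'   experimental arm's death times.
#' @param eos end of study (days).
#' @param gconfig a [gsearch_config()].
#' @return A list with `data` (the generated subject table, times in
#'   days) and `estimates` (named list of `"method_estimate"`s).
#' @export
run_case_study <- function(seed = 1L, n_control = 223, n_experimental = 231,
                           switch_prob = 167 / 201, hr_exp = 0.4,
                           eos = 730, gconfig = gsearch_config()) {
  set.seed(seed)
  r_prog <- log(2) / 53    # median time to progression 53 days
  r_death <- log(2) / 190  # median time to death 190 days
  r_switch <- log(2) / 49  # median residual survival after switching

  n <- n_control + n_experimental
  G <- rep(c(0L, 1L), c(n_control, n_experimental))
  entry <- stats::runif(n, 0, 365)
  C <- eos - entry

  prog <- stats::rexp(n, r_prog)
  death <- stats::rexp(n, ifelse(G == 1L, r_death * hr_exp, r_death))
  cause <- ifelse(prog < death, 1L, 2L)  # death after vs without progression

  ## control progressors may switch at progression; their residual
  ## survival is then re-drawn from the switcher distribution
  sw <- G == 0L & cause == 1L & stats::runif(n) < switch_prob
  W <- ifelse(sw, prog, NA_real_)
  resid <- stats::rexp(n, r_switch)
  lifetime <- ifelse(sw, prog + resid, death)

  late_sw <- sw & W >= C
  W[late_sw] <- NA_real_
  sw <- sw & !late_sw
  T_obs <- pmin(lifetime, C)
  delta <- ifelse(lifetime <= C, cause, 0L)
  dat <- data.frame(id = seq_len(n), G = G, entry = entry, C = C,
                    T = T_obs, delta = as.integer(delta), W = W,
                    t_unexposed = ifelse(G == 1L, 0, ifelse(sw, W, T_obs)),
                    t_exposed = ifelse(G == 1L, T_obs,
                                       ifelse(sw, T_obs - W, 0)))
  ests <- run_estimators(dat, all_methods, gconfig)
  list(data = dat, estimates = ests)
}
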