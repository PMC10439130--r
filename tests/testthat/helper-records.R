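# Hand-built subject records for unit tests of the counterfactual map.
# Columns mirror simulate_trial(); exposure durations are supplied
# directly so each record's structure is explicit.
subject_record <- function(G, T, delta, C = 100, W = NA_real_,
                           t_unexposed = NULL, t_exposed = NULL, id = 1L) {
  if (is.null(t_exposed)) t_exposed <- if (G == 1L) T else 0
  if (is.null(t_unexposed)) t_unexposed <- T - t_exposed
  data.frame(id = id, G = G, entry = 0, C = C, T = T, delta = delta,
             W = W, t_unexposed = t_unexposed, t_exposed = t_exposed)
}

bind_records <- function(...) {
  d <- do.call(rbind, list(...))
  d$id <- seq_len(nrow(d))
  d
}

# Small simulated trial for property tests.
sim_small <- function(seed, n_per_arm = 150, switch_pct = 0.3, hr_E = 0.5,
                      hr_C = 2, eos = 30) {
  cfg <- scenario_config(hr_E = hr_E, hr_C = hr_C, n_per_arm = n_per_arm,
                         switch_pct = switch_pct, eos = eos, seed = seed)
  set.seed(seed)
  simulate_trial(cfg)
}
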