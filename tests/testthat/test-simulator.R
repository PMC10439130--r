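test_that("calibrated hazards split in the target ratio and match the closed form", {
  cfg <- scenario_config(eos = 90, entry_max = 20, hr_E = 0.5, hr_C = 2)
  hz <- calibrate_hazards(0.5, 0.2, cfg)
  expect_equal(hz$h_s1 / hz$h_s2, 2.5)
  expect_equal(hz$h_m1, 0.5 * hz$h_s1)
  expect_equal(hz$h_m2, 2 * hz$h_s2)
  ## total hazard reproduces the requested overall event fraction,
  ## checked against numerical integration over C ~ U(70, 90)
  h <- hz$h_s1 + hz$h_s2
  p_any <- stats::integrate(function(c) (1 - exp(-h * c)) / 20, 70, 90)$value
  expect_equal(p_any, 0.7, tolerance = 1e-6)
})

test_that("degenerate or infeasible calibration targets are rejected", {
  cfg <- scenario_config()
  expect_error(calibrate_hazards(0.5, 0, cfg), "strictly positive")
  expect_error(calibrate_hazards(0.8, 0.3, cfg), "less than 1")
})

test_that("calibrated control arm reproduces the target event fractions", {
  cfg <- scenario_config(eos = 90, entry_max = 20, n_per_arm = 10000,
                         switch_pct = 0, hr_E = 1, hr_C = 1)
  hz <- calibrate_hazards(0.5, 0.2, cfg)
  set.seed(42)
  dat <- simulate_trial(cfg, hz)
  ctrl <- dat[dat$G == 0L, ]
  ## 3 binomial MC standard errors at n = 10,000
  expect_lt(abs(mean(ctrl$delta == 1L) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_lt(abs(mean(ctrl$delta == 2L) - 0.2), 3 * sqrt(0.16 / 10000))
})

test_that("latent failures follow the all-cause exponential with the stated cause split", {
  hz <- hazard_set(0.02, 0.008, 0.02, 0.008)
  set.seed(7)
  f <- draw_failure(hz, arm = 0, n = 1e5)
  expect_lt(abs(mean(f$time) - 1 / 0.028), 3 * (1 / 0.028) / sqrt(1e5))
  p1 <- 0.02 / 0.028
  expect_lt(abs(mean(f$cause == 1L) - p1), 3 * sqrt(p1 * (1 - p1) / 1e5))
})

test_that("switching stretches only the residual lifetime, by exp(-psi) of the cause", {
  cfg <- scenario_config(switch_pct = 1, beta_alpha = 2, beta_beta = 2)
  lat <- c(8, 14, 3, 22, 9)
  cause <- c(1L, 2L, 1L, 2L, 1L)
  set.seed(3)
  sw <- apply_switching(lat, cause, cfg, psi_E = -log(2), psi_C = log(1.5))
  expect_true(all(is.finite(sw$W)))
  mult <- ifelse(cause == 1L, 2, 1 / 1.5)
  expect_equal(sw$T, sw$W + mult * (lat - sw$W))
  expect_equal(sw$t_unexposed, sw$W)
  expect_equal(sw$t_exposed, sw$T - sw$W)
})

test_that("a null effect leaves switcher lifetimes bitwise unchanged", {
  cfg <- scenario_config(switch_pct = 1)
  lat <- rexp(200, 0.05)
  cause <- sample(1:2, 200, replace = TRUE)
  set.seed(5)
  sw <- apply_switching(lat, cause, cfg, psi_E = 0, psi_C = 0)
  expect_identical(sw$T, lat)
})

test_that("zero switching probability yields no switchers", {
  cfg <- scenario_config(switch_pct = 0)
  set.seed(5)
  sw <- apply_switching(rexp(100, 0.05), rep(1L, 100), cfg, -1, -1)
  expect_true(all(is.na(sw$W)))
  expect_true(all(sw$t_exposed == 0))
})

test_that("simulated trials respect the administrative censoring invariants", {
  dat <- sim_small(seed = 11, n_per_arm = 400)
  expect_true(all(dat$T <= dat$C))
  expect_true(all(dat$delta %in% 0:2))
  expect_equal(mean(dat$delta == 0) + mean(dat$delta == 1) +
                 mean(dat$delta == 2), 1)
  ## censored means the (possibly extended) lifetime crossed C
  expect_true(all(dat$T[dat$delta == 0L] == dat$C[dat$delta == 0L]))
  ## switchers switched strictly before their observed time and their
  ## exposure decomposition adds up
  sw <- !is.na(dat$W)
  expect_true(all(dat$W[sw] < dat$T[sw]))
  expect_equal(dat$t_unexposed[sw] + dat$t_exposed[sw], dat$T[sw])
  ## experimental arm is fully exposed, never switches
  exp_arm <- dat$G == 1L
  expect_true(all(is.na(dat$W[exp_arm])))
  expect_equal(dat$t_exposed[exp_arm], dat$T[exp_arm])
})

test_that("longer follow-up strictly reduces expected censoring", {
  cfg30 <- scenario_config(eos = 30, n_per_arm = 5000, switch_pct = 0,
                           hr_E = 1, hr_C = 1)
  hz <- calibrate_hazards(0.5, 0.2, cfg30)
  cfg90 <- scenario_config(eos = 90, n_per_arm = 5000, switch_pct = 0,
                           hr_E = 1, hr_C = 1)
  set.seed(8)
  cens30 <- mean(simulate_trial(cfg30, hz)$delta == 0L)
  cens90 <- mean(simulate_trial(cfg90, hz)$delta == 0L)
  expect_gt(cens30 - cens90, 0.05)
})

test_that("cause-1 share among control events matches the hazard ratio split", {
  cfg <- scenario_config(eos = 90, n_per_arm = 20000, switch_pct = 0,
                         hr_E = 1, hr_C = 1)
  hz <- calibrate_hazards(0.35, 0.35, cfg)
  set.seed(9)
  dat <- simulate_trial(cfg, hz)
  ctrl <- dat[dat$G == 0L & dat$delta != 0L, ]
  p <- hz$h_s1 / (hz$h_s1 + hz$h_s2)
  expect_lt(abs(mean(ctrl$delta == 1L) - p),
            3 * sqrt(p * (1 - p) / nrow(ctrl)))
})
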