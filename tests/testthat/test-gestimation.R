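test_that("the internal log-rank matches survdiff on adjusted data", {
  dat <- sim_small(seed = 41, n_per_arm = 120)
  for (psi in list(c(0, 0), c(-0.7, 0.7), c(0.3, -0.6))) {
    ao <- adjusted_outcome(dat, psi)
    for (k in 1:2) {
      if (sum(ao$Delta == k) < 2) next
      ref <- survival::survdiff(
        survival::Surv(ao$X, ao$Delta == k) ~ dat$G)$chisq
      mine <- rpsftcr:::logrank_z(ao$X, ao$Delta == k, dat$G)^2
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  }
})

test_that("the fast surface evaluator agrees with balance_test", {
  dat <- sim_small(seed = 42)
  psis <- matrix(c(0, 0, -0.7, 0.7, 0.4, -1.2, -2, -2), ncol = 2,
                 byrow = TRUE)
  fast <- rpsftcr:::eval_surface(dat, psis, "score", recensor = TRUE)
  ref <- apply(psis, 1, function(p) balance_test(dat, p)$statistic)
  expect_equal(fast, ref)
})

test_that("identical arms are perfectly balanced at psi = (0,0)", {
  ctrl <- sim_small(seed = 43, switch_pct = 0)
  ctrl <- ctrl[ctrl$G == 0L, ]
  dup <- rbind(ctrl, transform(ctrl, G = 1L, id = id + nrow(ctrl)))
  bt <- balance_test(dup, psi_pair(0, 0))
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p_value, 1)
})

test_that("the balance statistic is invariant to row order", {
  dat <- sim_small(seed = 44)
  set.seed(1)
  perm <- dat[sample(nrow(dat)), ]
  expect_equal(balance_test(perm, c(-0.4, 0.2))$statistic,
               balance_test(dat, c(-0.4, 0.2))$statistic)
})

test_that("the balance test refuses degenerate cause counts", {
  dat <- sim_small(seed = 45)
  one_arm <- dat[dat$G == 0L, ]
  expect_error(balance_test(one_arm, c(0, 0)), "both randomized arms")
  no2 <- dat
  no2$delta[no2$delta == 2L] <- 1L
  expect_error(balance_test(no2, c(0, 0)), "fewer than 2 events")
})

test_that("p-values at the true effect pair are approximately uniform", {
  ## with no switching the latent map at the truth restores balance,
  ## so over replications the test p-value should be near-uniform
  cfg <- scenario_config(hr_E = 0.5, hr_C = 1, n_per_arm = 100,
                         switch_pct = 0, eos = 30, seed = 31)
  hz <- calibrate_hazards(0.5, 0.2, cfg)
  truth <- c(log(0.5), 0)
  seeds <- rpsftcr:::replication_seeds(31, 200)
  p <- vapply(seeds, function(s) {
    set.seed(s)
    balance_test(simulate_trial(cfg, hz), truth)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the search result is reproducible and near-optimal on its own trace", {
  dat <- sim_small(seed = 46, n_per_arm = 100)
  g1 <- g_estimate(dat)
  g2 <- g_estimate(dat)
  expect_identical(g1$trace, g2$trace)
  expect_identical(unclass(g1$psi_hat), unclass(g2$psi_hat))
  ## the returned point is within the near-tie band of the global
  ## minimum, and never worse than the null point (0,0) plus that band
  cfg <- gsearch_config()
  expect_lte(g1$statistic, min(g1$trace$statistic) + cfg$tie_tol + 1e-12)
  expect_lte(g1$statistic,
             balance_test(dat, c(0, 0))$statistic + cfg$tie_tol + 1e-12)
})

test_that("coarse-to-fine search matches a brute-force 0.05 grid", {
  for (seed in c(47, 48)) {
    dat <- sim_small(seed = seed, n_per_arm = 60)
    g <- suppressWarnings(g_estimate(dat))
    ax <- seq(-3, 3, by = 0.05)
    brute <- min(rpsftcr:::eval_surface(
      dat, as.matrix(expand.grid(ax, ax)), "score", recensor = TRUE))
    expect_lte(min(g$trace$statistic), brute + 1e-12)
  }
})

test_that("a forced single-point grid returns that point", {
  dat <- sim_small(seed = 49, n_per_arm = 80)
  g <- suppressWarnings(
    g_estimate(dat, gsearch_config(lower = 0, upper = 0)))
  expect_equal(unclass(g$psi_hat), c(psi_E = 0, psi_C = 0))
  expect_true(g$boundary)
})

test_that("composite estimation reduces to the psi_E axis with one cause", {
  dat <- sim_small(seed = 50, hr_C = 1)
  dat$delta[dat$delta == 2L] <- 1L
  ## with no cause-2 events the joint statistic at (psi, psi) equals the
  ## composite statistic at psi
  cfg <- gsearch_config()
  for (psi in c(-0.9, -0.3, 0, 0.6)) {
    joint <- rpsftcr:::eval_surface(dat, matrix(c(psi, psi), 1), "score",
                                    recensor = TRUE)
    U <- exp(psi) * dat$t_exposed + dat$t_unexposed
    bound <- dat$C * exp(min(psi, 0))
    ev <- dat$delta != 0L
    X <- ifelse(ev, pmin(U, bound), bound)
    comp <- rpsftcr:::logrank_z(X, ev & U <= bound, dat$G)^2
    expect_equal(joint, comp)
  }
})

test_that("composite recovery finds a common effect and the permuted null is centred", {
  ## a common lifetime doubling on both causes, no switching
  cfg <- scenario_config(hr_E = 0.5, hr_C = 0.5, n_per_arm = 250,
                         switch_pct = 0, eos = 90, seed = 51)
  hz <- calibrate_hazards(0.5, 0.2, cfg)
  seeds <- rpsftcr:::replication_seeds(51, 30)
  psi <- null_psi <- numeric(30)
  for (r in 1:30) {
    set.seed(seeds[r])
    dat <- simulate_trial(cfg, hz)
    dat$delta[dat$delta == 2L] <- 1L
    psi[r] <- g_estimate_composite(dat)$psi_hat
    datp <- dat
    datp$G <- sample(dat$G)
    null_psi[r] <- suppressWarnings(g_estimate_composite(datp)$psi_hat)
  }
  expect_lt(abs(mean(psi) - log(0.5)), 0.08)
  expect_lt(abs(mean(null_psi)), 0.15)
})
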