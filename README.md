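# rpsftcr

Cause-specific treatment-effect estimation for randomized trials with
**treatment switching** and **competing risks**.

In many oncology trials, control-arm patients may cross over to the
experimental treatment at disease progression.  Intention-to-treat
(ITT) then dilutes the effect and censoring at switch (PP-cen) is
informative.  The rank-preserving structural failure time (RPSFT) model
repairs this causally — each subject owns a latent untreated lifetime
`U = exp(psi) * t_exposed + t_unexposed`, with `exp(-psi)` the
multiplicative lifetime benefit of treatment — but classically handles
only a single failure type.  `rpsftcr` extends RPSFT to two competing
causes on the cause-specific-hazards (CSH) scale: a pair
`(psi_E, psi_C)` acts on subjects according to the cause they
experienced, and is estimated by **two-dimensional G-estimation** — a
grid search for the pair at which re-censored latent times are maximally
balanced across randomized arms (joint cause-specific log-rank
statistic, `Z1^2 + Z2^2`).  Cause-specific hazard ratios are then
fitted by Cox regression on the switching-adjusted data (observed times
in the experimental arm, adjusted re-censored times in the control
arm), with `psi = log(HR) / gamma`.

The package also provides:

* a trial simulator (exponential cause-specific hazards, staggered
  uniform entry, administrative censoring, beta-timed
  progression-triggered switching with AFT lifetime extension);
* the naive comparators ITT and PP-cen, on cause-specific and
  composite endpoints (`ITT-com`, `PPcen-com`, `RPSFT-com`);
* Monte Carlo performance summaries (mean HR, SD, MSE, relative bias,
  coverage, censoring) and an 18-scenario study grid;
* a synthetic colorectal-cancer case-study demo;
* a small CLI (`exec/rpsftcr`) over the same functions.

## Worked example

```r
library(rpsftcr)

cfg <- scenario_config(hr_E = 0.5, hr_C = 2, n_per_arm = 250,
                       switch_pct = 0.3, eos = 30, seed = 2)
set.seed(2)
dat <- simulate_trial(cfg)   # 500 subjects, ~30% of controls switch

estimate_itt(dat)
#> ITT: HR = 0.538 (95% CI 0.398-0.727), 34.0% censored
#>   competing-event HR = 1.694

estimate_rpsft(dat)
#> RPSFT: HR = 0.579 (95% CI 0.402-0.835), 44.6% censored
#>   competing-event HR = 0.774
#>   psi_hat = -1.067, 0.339
```

The true cause-1 hazard ratio here is 0.5, the competing-event ratio 2.
`psi_hat` is the balance point of the two-dimensional G-estimation
(`exp(psi_E)` shrinks each switcher's exposed time before the final
cause-specific Cox fit; on a single 500-subject dataset it is noisy —
the Wald interval of the HR is the meaningful uncertainty statement).
Censoring rises under RPSFT because re-censoring converts some control
events into artificial censorings.  Replication summaries come from

```r
res <- run_scenario(cfg, n_reps = 200)
res$summary   # mean HR, SD, MSE, relative bias %, coverage, censoring per method
```

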