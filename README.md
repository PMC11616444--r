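# batforage

Colony-level central-place foraging analysis from GPS telemetry.

Cave-roosting bats such as the greater spear-nosed bat (*Phyllostomus
hastatus*) leave their roost every evening, commute 15–25 km in nearly
straight flight to a colony-specific foraging area, forage there in short
tortuous movements, and return before dawn. `batforage` implements the full
analysis chain for such data, for movement ecologists asking whether
colonies share foraging space and whether they use the landscape that was
available to them:

* **Track ingestion and cleaning** — Movebank-dialect CSV, metric
  (transverse-Mercator) projection, a sequential 15 m/s speed filter,
  an over-water range rule, downsampling, and regularization onto a fixed
  time grid with explicit missing slots.
* **Behavioural segmentation** — a two-state hidden Markov model with
  gamma step lengths and wrapped Cauchy turning angles per state,

  $$\ell_t \mid s_t \sim \Gamma(k_{s_t}, \beta_{s_t}), \quad
    \varphi_t \mid s_t \sim \mathrm{wC}(\mu_{s_t}, \rho_{s_t}),$$

  fitted by direct maximization of the pooled forward log-likelihood and
  decoded by Viterbi + forward–backward smoothing. State 1 is *foraging*
  (short, tortuous, including rest), state 2 *commuting* (long, straight).
* **Foraging metrics** — commute straightness indices, foraging-location
  extraction (first fix of each multi-slot foraging bout), bearings and
  distances to the roost (south-zero clockwise convention; compass degrees
  = rad·180/π + 180), on/off-island foraging time with binomial GLMs, and
  a balsa-tree energetics utility.
* **Null-track simulation** — generative runs of the fitted kernel,
  constrained by the coastline (no foraging over water) with a
  return-to-roost bias, representing available rather than used space.
* **Hierarchical Bayesian inference** — per colony × season × provenance,

  $$d_{ij} \sim N(\mu_d + b_i, \sigma_d), \quad
    \theta_{ij} \sim \mathrm{vM}(\mu_\theta + a_i, \kappa),$$

  with Gaussian individual random effects and weakly regularizing priors,
  sampled by an adaptive Metropolis-within-Gibbs MCMC with split-R̂ and ESS
  diagnostics; population means, effective SDs, individual-level
  variability, and wrapped posterior contrasts.
* **Spatial overlap** — rasterized products of the distance and bearing
  predictive densities, 95% highest-density contours, and asymmetric
  pairwise overlap percentages clipped to land.
* **Synthetic data** — a landscape and trajectory generator with known
  ground truth (per-fix behavioural states, per-night anchors, per-bat
  means) so the whole pipeline is testable without any field data.

## Worked example

Simulate one dry-season colony, segment its nights, and fit the
distance/bearing model:

```r
library(batforage)

ls1 <- make_landscape(seed = 1)            # island + mainland + 3 roosts
sc  <- colony_scenario("colony1", season = "dry", n_individuals = 3,
                       nights_per_individual = 2,
                       commute_angle_mean = 1.45, mean_commute_distance = 23)
d <- simulate_dataset(list(sc), movement_kernel(), ls1, seed = 42)

series <- lapply(d$tracks, function(tr)
  regularize(downsample(remove_outliers(tr, ls1), 120)))
hmm <- fit_hmm(series, n_states = 2, n_restarts = 2, seed = 1)
hmm
#> <bat_hmm> 2-state movement HMM (6 series, 2154 slots)
#>   foraging   step ~ Gamma(shape=1.2, scale=94.4) [mean 113 m]; turn ~ wC(mu=0.04, rho=0.10)
#>   commuting  step ~ Gamma(shape=9.44, scale=78) [mean 736 m]; turn ~ wC(mu=0.00, rho=0.87)
#>   logLik -17176.88, 10 parameters, AIC 34373.77

states <- lapply(series, decode_states, model = hmm)
locs <- do.call(rbind, lapply(seq_along(series), function(i)
  extract_foraging_locations(series[[i]], states[[i]],
                             ls1$roosts$colony1, ls1,
                             meta = list(individual_id = d$tracks[[i]]$individual_id))))
fit <- fit_hier(locs, draws = 800, warmup = 800, chains = 2, seed = 3)
fit
#> <bat_hier> 69 locations, 3 individuals, 2 chains
#>   distance: mean 22.83 km [20.94-26.78], effective SD 1.93 km, tau 1.24 km
#>   bearing:  mean 1.37 rad (258.6 deg) [0.85-1.79], effective SD 0.38 rad, tau 0.29 rad
#>   max split-Rhat 1.030
```

The foraging state captures the short (~113 m per 2 min) tortuous
movements, the commuting state the long (~736 m ≈ 6 m/s) directionally
persistent flight. The hierarchical fit recovers the generator's
conditions: a ~23 km mean foraging distance on a west-southwest bearing
(1.45 rad ≈ 263°), with the effective SD combining residual and
between-individual spread. `run_colony_pipeline()` chains all stages —
including null cohorts and colony-overlap rasters — in one call;
`contrasts_hier()` compares seasons, colonies, or observed versus simulated
cohorts.

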