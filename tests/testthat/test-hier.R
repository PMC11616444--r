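test_that("effective circular SD matches the Bessel closed form", {
  mc <- effective_circular_sd(2, 0, n_mc = 5e4, seed = 1)
  closed <- sqrt(-2 * log(besselI(2, 1) / besselI(2, 0)))
  expect_equal(mc, closed, tolerance = 0.02)
  # concentration limit: SD ~ 1/sqrt(kappa)
  expect_equal(effective_circular_sd(1e4, 0, n_mc = 5e4, seed = 2), 0.01,
               tolerance = 0.05)
  # between-individual dispersion strictly inflates the SD
  expect_gt(effective_circular_sd(5, 0.5, n_mc = 2e4, seed = 3),
            effective_circular_sd(5, 0, n_mc = 2e4, seed = 3))
  expect_error(effective_circular_sd(0, 0.1), "kappa")
})

test_that("posterior intervals cover the generating parameters", {
  loc <- gen_hier_data(101)
  fit <- fit_hier(loc, draws = 800, warmup = 800, chains = 2, seed = 5)
  truth <- c(mu_d = 22, sigma_d = 2, tau_d = 1.5, mu_theta = 1.5,
             kappa = 8, tau_theta = 0.2)
  ci <- confint(fit)
  for (p in names(truth))
    expect_true(ci[p, 1] <= truth[[p]] && truth[[p]] <= ci[p, 2],
                label = paste("interval covers", p))
  expect_lt(max(fit$rhat), 1.05)
  s <- summary(fit)
  expect_equal(s["mu_theta", "compass_deg"],
               s["mu_theta", "mean"] * 180 / pi + 180)
})

test_that("bearings at the wrap point are summarized without artefacts", {
  loc <- gen_hier_data(7, mu_theta = pi - 0.05)
  fit <- fit_hier(loc, draws = 600, warmup = 600, chains = 2, seed = 8)
  expect_equal(abs(fit$summary["mu_theta", "mean"]), pi - 0.05,
               tolerance = 0.15)
  lo <- fit$summary["mu_theta", "q2.5"]; hi <- fit$summary["mu_theta", "q97.5"]
  width <- wrap_angle(hi - lo); width <- ifelse(width < 0, width + 2 * pi, width)
  expect_lt(width, 0.5)
})

test_that("zero-variance generators concentrate tau near zero", {
  loc <- gen_hier_data(13, tau_d = 0, tau_theta = 0)
  fit <- fit_hier(loc, draws = 600, warmup = 600, chains = 2, seed = 9)
  ci <- confint(fit)
  expect_lt(ci["tau_d", 2], fit$summary["sigma_d", "mean"])
  expect_lt(ci["tau_theta", 2], 0.25)
})

test_that("single-individual data warn about unidentifiable tau", {
  loc <- gen_hier_data(3, I = 1, J = 8)
  # tau is confounded with the single intercept, so the fit may also
  # legitimately report nonconvergence; capture all warnings
  w <- capture_warnings(fit_hier(loc, draws = 200, warmup = 200, chains = 2,
                                 seed = 1, on_nonconverged = "warn"))
  expect_true(any(grepl("unidentifiable", w)))
  expect_error(fit_hier(loc[1:2, ], seed = 1), "at least 3")
})

test_that("contrasts are exact for identity and wrap around the seam", {
  loc <- gen_hier_data(21)
  fit <- fit_hier(loc, draws = 500, warmup = 500, chains = 2, seed = 11)
  ct <- contrasts_hier(fit, fit)
  expect_true(all(abs(ct$mean) < 1e-12))
  expect_true(all(abs(ct$q97.5 - ct$q2.5) < 1e-12))
  # +3 km distance shift is detected and covered
  fit2 <- fit_hier(gen_hier_data(22, mu_d = 25), draws = 500, warmup = 500,
                   chains = 2, seed = 12)
  cd <- contrasts_hier(fit2, fit)
  row <- cd[cd$parameter == "mu_d", ]
  expect_true(row$q2.5 <= 3 && 3 <= row$q97.5)
  expect_gt(row$q2.5, 0)
  # angular difference wraps: (pi - 0.1) vs (-pi + 0.1) is -0.2, not 2pi - 0.2
  fa <- fit_hier(gen_hier_data(23, mu_theta = pi - 0.1, kappa = 20),
                 draws = 500, warmup = 500, chains = 2, seed = 13)
  fb <- fit_hier(gen_hier_data(24, mu_theta = -pi + 0.1, kappa = 20),
                 draws = 500, warmup = 500, chains = 2, seed = 14)
  ca <- contrasts_hier(fa, fb)
  expect_lt(abs(ca$mean[ca$parameter == "mu_theta"] + 0.2), 0.15)
})

test_that("the priors are weakly regularizing, not flat", {
  set.seed(5)
  pr <- batforage:::.default_priors()
  mu <- stats::rnorm(4000, pr$mu_d[1], pr$mu_d[2])
  sig <- abs(stats::rnorm(4000, 0, pr$sigma_d))
  tau <- abs(stats::rnorm(4000, 0, pr$tau_d))
  d <- stats::rnorm(4000, mu + stats::rnorm(4000, 0, tau), sig)
  expect_gt(mean(d > 0 & d < 80), 0.75)
  expect_lt(stats::sd(d), 50)
})
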