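test_that("forward log-likelihood equals the enumeration oracle", {
  set.seed(21)
  for (r in 1:30) {
    p <- random_hmm_pars()
    obs <- random_obs(sample(1:6, 1))
    ll_fwd <- batforage:::.forward_ll(
      batforage:::.hmm_logE(obs, p$shape, p$scale, p$mu, p$rho), p$Gamma, p$delta)
    expect_equal(ll_fwd, enum_loglik(p, obs), tolerance = 1e-10)
  }
})

test_that("missing observations contribute probability one", {
  p <- random_hmm_pars()
  obs <- cbind(step = rep(NA_real_, 5), angle = rep(NA_real_, 5))
  ll <- batforage:::.forward_ll(
    batforage:::.hmm_logE(obs, p$shape, p$scale, p$mu, p$rho), p$Gamma, p$delta)
  expect_equal(ll, 0)
})

test_that("a one-state model collapses to independent emission densities", {
  s <- simulate_steps(bf_kernel, 120, seed = 5)
  m1 <- fit_hmm(s, n_states = 1, n_restarts = 1, seed = 1)
  o <- batforage:::.hmm_obs(s)
  ll_ind <- sum(stats::dgamma(o[!is.na(o[, 1]), 1], shape = m1$shape,
                              scale = m1$scale, log = TRUE)) +
    sum(dwrappedcauchy(o[!is.na(o[, 2]), 2], m1$mu, m1$rho, log = TRUE))
  expect_equal(hmm_loglik(m1, s), ll_ind, tolerance = 1e-8)
  expect_true(all(decode_states(m1, s)$state == 1))
})

test_that("Viterbi decoding equals the brute-force most probable path", {
  set.seed(33)
  for (r in 1:15) {
    p <- random_hmm_pars()
    obs <- random_obs(4, miss = FALSE)
    ser <- obs_as_series(obs)
    o2 <- batforage:::.hmm_obs(ser)
    m <- c(p, list(n_states = 2)); class(m) <- "bat_hmm"
    dec <- decode_states(m, ser)
    expect_equal(dec$state[1:4], unname(enum_viterbi(p, o2)))
    expect_equal(rowSums(dec[, c("p1", "p2")]), rep(1, 5), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under state relabelling", {
  p <- random_hmm_pars()
  s <- simulate_steps(bf_kernel, 100, seed = 3)
  m <- c(p, list(n_states = 2)); class(m) <- "bat_hmm"
  perm <- list(shape = rev(p$shape), scale = rev(p$scale), mu = rev(p$mu),
               rho = rev(p$rho), Gamma = p$Gamma[2:1, 2:1],
               delta = p$delta[2:1], n_states = 2)
  class(perm) <- "bat_hmm"
  expect_equal(hmm_loglik(m, s), hmm_loglik(perm, s))
})

test_that("fitted states are labelled foraging-first by mean step length", {
  sl <- lapply(1:2, function(i) simulate_steps(bf_kernel, 240, seed = 40 + i))
  m <- fit_hmm(sl, n_states = 2, n_restarts = 1, seed = 1)
  expect_lt(m$shape[1] * m$scale[1], m$shape[2] * m$scale[2])
  expect_equal(m$AIC, 2 * m$npar - 2 * m$logLik)
  expect_equal(rowSums(m$Gamma), c(1, 1), tolerance = 1e-10)
  expect_equal(sum(m$delta), 1, tolerance = 1e-10)
})

test_that("decoding separates well-separated regimes near perfectly", {
  sl <- lapply(1:3, function(i) simulate_steps(bf_kernel, 300, seed = 50 + i))
  m <- fit_hmm(sl, n_states = 2, n_restarts = 1, seed = 1)
  acc <- vapply(sl, function(s)
    mean(decode_states(m, s)$state == attr(s, "truth_states")), 0)
  expect_gte(mean(acc), 0.95)
})

test_that("imputed slots are flagged and bridged by Viterbi", {
  s <- simulate_steps(bf_kernel, 150, seed = 9)
  s$step[40:45] <- NA; s$angle[40:46] <- NA
  m <- fit_hmm(s, n_states = 2, n_restarts = 1, seed = 1)
  dec <- decode_states(m, s)
  expect_true(all(dec$imputed[41:45]))
  expect_true(all(dec$state[41:45] %in% 1:2))
})

test_that("degenerate constant steps abort the fit", {
  s <- simulate_steps(bf_kernel, 100, seed = 2)
  s$step[] <- 100
  expect_error(fit_hmm(s), "degeneracy")
})

test_that("zero step lengths are shifted off the gamma singularity", {
  s <- simulate_steps(bf_kernel, 60, seed = 4)
  s$step[10] <- 0
  o <- batforage:::.hmm_obs(s)
  expect_gt(min(o[, 1], na.rm = TRUE), 0)
})
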