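# Shared fixtures: built once per test run.

# default synthetic landscape (island + L-shaped mainland, UTM 17N)
bf_ls <- make_landscape(1)

# the generator's default two-state movement kernel with delta attached
bf_kernel <- local({
  k <- movement_kernel()
  k$delta <- batforage:::.stationary(k$Gamma)
  k
})

# brute-force forward log-likelihood by enumeration over all state paths
enum_loglik <- function(p, obs) {
  n <- length(p$shape); Tn <- nrow(obs)
  logE <- batforage:::.hmm_logE(obs, p$shape, p$scale, p$mu, p$rho)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn)))
  lps <- apply(paths, 1, function(s) {
    lp <- log(p$delta[s[1]]) + logE[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      lp <- lp + log(p$Gamma[s[t - 1], s[t]]) + logE[t, s[t]]
    lp
  })
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# brute-force most probable state path
enum_viterbi <- function(p, obs) {
  n <- length(p$shape); Tn <- nrow(obs)
  logE <- batforage:::.hmm_logE(obs, p$shape, p$scale, p$mu, p$rho)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn)))
  lps <- apply(paths, 1, function(s) {
    lp <- log(p$delta[s[1]]) + logE[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      lp <- lp + log(p$Gamma[s[t - 1], s[t]]) + logE[t, s[t]]
    lp
  })
  paths[which.max(lps), ]
}

# random valid 2-state HMM parameters
random_hmm_pars <- function() {
  G <- matrix(stats::runif(4, 0.1, 0.9), 2)
  G <- G / rowSums(G)
  list(shape = stats::runif(2, 0.5, 5), scale = stats::runif(2, 10, 500),
       mu = stats::runif(2, -pi, pi), rho = stats::runif(2, 0, 0.9),
       Gamma = G, delta = batforage:::.stationary(G))
}

# random observation matrix (step, angle) with optional missingness
random_obs <- function(Tn, miss = TRUE) {
  obs <- cbind(step = stats::rgamma(Tn, 2, 0.01),
               angle = stats::runif(Tn, -pi, pi))
  if (miss && Tn > 2) {
    obs[2, 1] <- NA
    if (stats::runif(1) < 0.5) obs[2, 2] <- NA
  }
  obs
}

# wrap a bare observation matrix as a bat_steps series
obs_as_series <- function(obs) {
  Tn <- nrow(obs)
  structure(data.frame(
    time = as.POSIXct("2022-03-01 23:00:00", tz = "UTC") + 0:Tn * 120,
    x = 0, y = 0, obs = TRUE,
    step = c(obs[, 1], NA), angle = c(NA, obs[-1, 2], NA)),
    interval = 120, class = c("bat_steps", "data.frame"))
}

# a hand-built track from coordinate vectors at a fixed interval
make_track <- function(x, y, interval = 120, colony = "colony1",
                       t0 = as.POSIXct("2022-03-01 23:00:00", tz = "UTC")) {
  fx <- data.frame(time = t0 + (seq_along(x) - 1) * interval,
                   lon = NA_real_, lat = NA_real_, x = x, y = y,
                   speed = NA_real_)
  batforage:::new_track("t1", colony, "dry", "p", as.Date("2022-03-01"),
                        fx, interval = interval)
}

# hierarchical-model generator at the reference simulation settings
gen_hier_data <- function(seed, mu_d = 22, sigma_d = 2, tau_d = 1.5,
                          mu_theta = 1.5, kappa = 8, tau_theta = 0.2,
                          I = 20, J = 8) {
  set.seed(seed)
  b <- stats::rnorm(I, 0, tau_d)
  a <- stats::rnorm(I, 0, tau_theta)
  data.frame(individual_id = rep(seq_len(I), each = J),
             distance_km = stats::rnorm(I * J, mu_d + rep(b, each = J), sigma_d),
             angle_rad = wrap_angle(rep(mu_theta + a, each = J) +
                                      rvonmises(I * J, 0, kappa)))
}
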