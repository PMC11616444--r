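# Hierarchical Bayesian model of foraging distance and bearing.
#
# Distance (km):  d_ij ~ Normal(mu_d + b_i, sigma_d),  b_i ~ Normal(0, tau_d)
# Bearing (rad):  theta_ij ~ vonMises(mu_th + a_i, kappa), a_i ~ Normal(0, tau_th)
# i = individual, j = repeated foraging locations within individual. The two
# components share the individual index but are conditionally independent.
#
# Weakly regularizing priors: mu_d ~ N(20, 20) km; sigma_d, tau_d ~
# HalfNormal(10) km; mu_th ~ N(0, 2) rad; kappa ~ HalfNormal(10);
# tau_th ~ HalfNormal(1) rad.
#
# Posterior sampling: adaptive random-walk Metropolis within Gibbs with the
# random effects in non-centred form (b_i = tau_d * u_i, u_i ~ N(0,1));
# scalar hyperparameters and the full random-effect vector are updated in
# turn, with proposal scales tuned to ~44% acceptance during warmup.

.default_priors <- function() {
  list(mu_d = c(20, 20), sigma_d = 10, tau_d = 10,
       mu_theta = c(0, 2), kappa = 10, tau_theta = 1)
}

# one chain of the Gaussian distance component; returns draws matrix.
# mu and the non-centred effects u are conditionally conjugate and are
# Gibbs-sampled; sigma and tau move by adaptive random-walk Metropolis.
.chain_distance <- function(d, ind, priors, n_iter, warmup, seed) {
  set.seed(seed)
  ids <- unique(ind)
  fi <- factor(ind, levels = ids)
  ni <- as.vector(table(fi))
  S1 <- as.vector(tapply(d, fi, sum))
  S2 <- as.vector(tapply(d^2, fi, sum))
  I <- length(ids); N <- length(d)
  llik <- function(mu, tau, sigma, u) {
    m <- mu + tau * u
    -N * log(sigma) - sum(S2 - 2 * m * S1 + ni * m^2) / (2 * sigma^2)
  }
  lpost <- function(mu, ls, lt, u) {
    sigma <- exp(ls); tau <- exp(lt)
    llik(mu, tau, sigma, u) +
      stats::dnorm(mu, priors$mu_d[1], priors$mu_d[2], log = TRUE) +
      stats::dnorm(sigma, 0, priors$sigma_d, log = TRUE) + ls +
      stats::dnorm(tau, 0, priors$tau_d, log = TRUE) + lt +
      sum(stats::dnorm(u, log = TRUE))
  }
  mu <- mean(d); ls <- log(max(stats::sd(d), 0.5)); lt <- log(1); u <- rep(0, I)
  sc <- c(ls = 0.3, lt = 0.4)
  acc <- c(0, 0); batch <- 0
  keep <- matrix(NA_real_, n_iter - warmup, 3 + I)
  for (it in seq_len(n_iter)) {
    sigma <- exp(ls); tau <- exp(lt)
    # Gibbs: mu | u, sigma, tau
    prec <- N / sigma^2 + 1 / priors$mu_d[2]^2
    mhat <- (sum(S1 - ni * tau * u) / sigma^2 +
               priors$mu_d[1] / priors$mu_d[2]^2) / prec
    mu <- stats::rnorm(1, mhat, 1 / sqrt(prec))
    # Gibbs: u_i | mu, sigma, tau
    prec_u <- 1 + ni * tau^2 / sigma^2
    uhat <- (tau / sigma^2) * (S1 - ni * mu) / prec_u
    u <- stats::rnorm(I, uhat, 1 / sqrt(prec_u))
    # Metropolis: log sigma, log tau
    lp <- lpost(mu, ls, lt, u)
    for (k in 1:2) {
      prop <- c(ls, lt)
      prop[k] <- prop[k] + stats::rnorm(1, 0, sc[k])
      lp2 <- lpost(mu, prop[1], prop[2], u)
      if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
        ls <- prop[1]; lt <- prop[2]
        lp <- lp2; acc[k] <- acc[k] + 1
      }
    }
    # shift move: slides mu against the effects at fixed fitted means,
    # breaking the mu <-> u anticorrelation of the Gibbs alternation
    tau <- exp(lt)
    dl <- stats::rnorm(1, 0, 0.5)
    mu2 <- mu + dl; us <- u - dl / tau
    dlp <- stats::dnorm(mu2, priors$mu_d[1], priors$mu_d[2], log = TRUE) -
      stats::dnorm(mu, priors$mu_d[1], priors$mu_d[2], log = TRUE) +
      sum(stats::dnorm(us, log = TRUE)) - sum(stats::dnorm(u, log = TRUE))
    if (log(stats::runif(1)) < dlp) { mu <- mu2; u <- us }
    # rescale move: tau' = tau e^e, u' = u e^-e leaves the fitted means
    # unchanged; acceptance includes the Jacobian exp(-I e)
    e <- stats::rnorm(1, 0, 0.3)
    lt2 <- lt + e; us <- u * exp(-e)
    dlp <- stats::dnorm(exp(lt2), 0, priors$tau_d, log = TRUE) + lt2 -
      stats::dnorm(exp(lt), 0, priors$tau_d, log = TRUE) - lt +
      sum(stats::dnorm(us, log = TRUE)) - sum(stats::dnorm(u, log = TRUE)) -
      I * e
    if (is.finite(dlp) && log(stats::runif(1)) < dlp) { lt <- lt2; u <- us }
    batch <- batch + 1
    if (it <= warmup && batch == 50) {  # proposal-scale adaptation
      r <- acc / 50
      sc <- sc * ifelse(r > 0.5, 1.3, ifelse(r < 0.3, 1 / 1.3, 1))
      acc <- c(0, 0); batch <- 0
    }
    if (it > warmup) keep[it - warmup, ] <- c(mu, exp(ls), exp(lt), u)
  }
  colnames(keep) <- c("mu_d", "sigma_d", "tau_d", paste0("u", seq_len(I)))
  attr(keep, "ids") <- ids
  keep
}

# one chain of the von Mises bearing component
.chain_angle <- function(th, ind, priors, n_iter, warmup, seed) {
  set.seed(seed)
  ids <- unique(ind)
  fi <- factor(ind, levels = ids)
  C <- as.vector(tapply(cos(th), fi, sum))
  S <- as.vector(tapply(sin(th), fi, sum))
  I <- length(ids); N <- length(th)
  llik <- function(mu, tau, kap, v) {
    m <- mu + tau * v
    kap * sum(C * cos(m) + S * sin(m)) -
      N * (log(besselI(kap, 0, expon.scaled = TRUE)) + kap + log(2 * pi))
  }
  lpost <- function(mu, lk, lt, v) {
    kap <- exp(lk); tau <- exp(lt)
    llik(mu, tau, kap, v) +
      stats::dnorm(mu, priors$mu_theta[1], priors$mu_theta[2], log = TRUE) +
      stats::dnorm(kap, 0, priors$kappa, log = TRUE) + lk +
      stats::dnorm(tau, 0, priors$tau_theta, log = TRUE) + lt +
      sum(stats::dnorm(v, log = TRUE))
  }
  mu <- circ_mean(th)
  R <- max(min(circ_R(th), 0.99), 0.05)
  lk <- log(max((R * (2 - R^2)) / (1 - R^2), 0.5))  # A1-inverse approximation
  lt <- log(0.3); v <- rep(0, I)
  sc <- c(mu = 0.3, lk = 0.3, lt = 0.4); sc_v <- 0.5
  acc <- c(0, 0, 0); acc_v <- 0; batch <- 0
  lp <- lpost(mu, lk, lt, v)
  keep <- matrix(NA_real_, n_iter - warmup, 3 + I)
  for (it in seq_len(n_iter)) {
    for (k in 1:3) {
      prop <- c(mu, lk, lt)
      prop[k] <- prop[k] + stats::rnorm(1, 0, sc[k])
      lp2 <- lpost(prop[1], prop[2], prop[3], v)
      if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
        mu <- prop[1]; lk <- prop[2]; lt <- prop[3]
        lp <- lp2; acc[k] <- acc[k] + 1
      }
    }
    kap <- exp(lk); tau <- exp(lt)
    v2 <- v + stats::rnorm(I, 0, sc_v)
    m1 <- mu + tau * v; m2 <- mu + tau * v2
    lp_i1 <- kap * (C * cos(m1) + S * sin(m1)) + stats::dnorm(v, log = TRUE)
    lp_i2 <- kap * (C * cos(m2) + S * sin(m2)) + stats::dnorm(v2, log = TRUE)
    take <- log(stats::runif(I)) < lp_i2 - lp_i1
    v[take] <- v2[take]
    acc_v <- acc_v + mean(take)
    # joint shift move: slides mu against the effects at fixed fitted means,
    # breaking the mu <-> v posterior coupling (likelihood is unchanged)
    dl <- stats::rnorm(1, 0, 0.3)
    mu2 <- mu + dl; vs <- v - dl / tau
    dlp <- stats::dnorm(mu2, priors$mu_theta[1], priors$mu_theta[2], log = TRUE) -
      stats::dnorm(mu, priors$mu_theta[1], priors$mu_theta[2], log = TRUE) +
      sum(stats::dnorm(vs, log = TRUE)) - sum(stats::dnorm(v, log = TRUE))
    if (log(stats::runif(1)) < dlp) { mu <- mu2; v <- vs }
    # rescale move for tau (see distance chain)
    e <- stats::rnorm(1, 0, 0.3)
    lt2 <- lt + e; vs <- v * exp(-e)
    dlp <- stats::dnorm(exp(lt2), 0, priors$tau_theta, log = TRUE) + lt2 -
      stats::dnorm(exp(lt), 0, priors$tau_theta, log = TRUE) - lt +
      sum(stats::dnorm(vs, log = TRUE)) - sum(stats::dnorm(v, log = TRUE)) -
      I * e
    if (is.finite(dlp) && log(stats::runif(1)) < dlp) { lt <- lt2; v <- vs }
    lp <- lpost(mu, lk, lt, v)
    batch <- batch + 1
    if (it <= warmup && batch == 50) {
      r <- acc / 50; rv <- acc_v / 50
      sc <- sc * ifelse(r > 0.5, 1.3, ifelse(r < 0.3, 1 / 1.3, 1))
      sc_v <- sc_v * if (rv > 0.5) 1.3 else if (rv < 0.3) 1 / 1.3 else 1
      acc <- c(0, 0, 0); acc_v <- 0; batch <- 0
    }
    if (it > warmup) keep[it - warmup, ] <- c(mu, exp(lk), exp(lt), v)
  }
  colnames(keep) <- c("mu_theta", "kappa", "tau_theta", paste0("v", seq_len(I)))
  attr(keep, "ids") <- ids
  keep
}

#' Split-Rhat and effective sample size
#'
#' Standard split-chain potential scale reduction factor and a
#' Geyer-truncated autocorrelation effective sample size.
#'
#' @param x draws matrix (iterations x chains).
#' @return scalar R-hat (`split_rhat`) or ESS (`ess_basic`).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu_j <- colMeans(halves)
  B <- n * stats::var(mu_j)
  W <- mean(apply(halves, 2, stats::var))
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname split_rhat
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  rho_sum <- 0
  for (j in seq_len(m)) {
    v <- x[, j] - mean(x[, j])
    if (stats::sd(v) < 1e-12) next
    ac <- stats::acf(v, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
    # Geyer: stop at the first negative pair sum
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  rho_sum <- rho_sum / m
  m * n / (1 + 2 * rho_sum)
}

#' Effective circular standard deviation of the bearing predictive
#'
#' Spread of the marginal observation-level bearing distribution combining
#' the von Mises concentration `kappa` with between-individual dispersion
#' `tau_theta`: simulates `a ~ N(0, tau_theta)`, `theta ~ VM(a, kappa)` and
#' returns the circular SD of the pooled sample. With `tau_theta = 0` this
#' converges to the closed form `sqrt(-2 log(I1(kappa)/I0(kappa)))`.
#'
#' @param kappa von Mises concentration (> 0).
#' @param tau_theta between-individual SD (rad, >= 0).
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @return circular SD in radians.
#' @export
effective_circular_sd <- function(kappa, tau_theta, n_mc = 10000, seed = 1) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (tau_theta < 0) stop("tau_theta must be >= 0", call. = FALSE)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  a <- stats::rnorm(n_mc, 0, tau_theta)
  th <- a + rvonmises(n_mc, 0, kappa)
  circ_sd(th)
}

# closed form for the same quantity: Rbar = exp(-tau^2/2) * A1(kappa)
.eff_circ_sd_closed <- function(kappa, tau_theta) {
  A1 <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(tau_theta^2 - 2 * log(A1))
}

.wrapped_summary <- function(draws) {
  ctr <- circ_mean(draws)
  dev <- wrap_angle(draws - ctr)
  q <- stats::quantile(dev, c(0.025, 0.975))
  c(mean = wrap_angle(ctr + mean(dev)), q2.5 = wrap_angle(ctr + q[[1]]),
    q97.5 = wrap_angle(ctr + q[[2]]))
}

#' Fit the hierarchical foraging distance/bearing model
#'
#' Fits the Gaussian distance and von Mises bearing components on one group
#' of foraging locations (one colony x season x provenance), with individual
#' random effects, by adaptive MCMC. Convergence is checked with split-Rhat
#' on every parameter; if any hyperparameter exceeds 1.05 the fit is rerun
#' once with doubled iterations before failing (or warning, per
#' `on_nonconverged`).
#'
#' @param locations data frame with columns `distance_km`, `angle_rad`,
#'   `individual_id`; if an `on_home_island` column is present and
#'   `off_island_only = TRUE` (default), on-island rows are dropped first
#'   (off-island locations represent the bulk of foraging and the model's
#'   Gaussian distance likelihood is meant for them).
#' @param draws posterior draws per chain (after warmup).
#' @param warmup warmup iterations per chain.
#' @param chains number of chains.
#' @param seed integer seed.
#' @param priors list overriding [.default_priors()] elements.
#' @param off_island_only drop on-island locations first?
#' @param on_nonconverged `"retry"` (default), `"error"`, or `"warn"`.
#' @param group optional named list of labels stored with the fit.
#' @return an object of class `"bat_hier"`: posterior `draws` (matrix with a
#'   `chain` column), `summary` (mean and central 95% interval for the
#'   population means, effective SDs and individual-level variabilities),
#'   `rhat`, `ess`, sample sizes and group labels.
#' @export
fit_hier <- function(locations, draws = 1000, warmup = 1000, chains = 2,
                     seed = 1, priors = list(), off_island_only = TRUE,
                     on_nonconverged = c("retry", "error", "warn"),
                     group = list()) {
  on_nonconverged <- match.arg(on_nonconverged)
  pr <- utils::modifyList(.default_priors(), priors)
  loc <- locations
  if (off_island_only && "on_home_island" %in% names(loc))
    loc <- loc[!loc$on_home_island, , drop = FALSE]
  if (nrow(loc) < 3)
    stop("need at least 3 foraging locations to fit", call. = FALSE)
  ind <- as.character(loc$individual_id)
  if (length(unique(ind)) < 2)
    warning("single individual: individual-level variability (tau) is ",
            "unidentifiable and will be prior-dominated")
  run <- function(n_draws, n_warm) {
    dl <- lapply(seq_len(chains), function(ch)
      .chain_distance(loc$distance_km, ind, pr, n_draws + n_warm, n_warm,
                      .substream(seed, 11L, ch)))
    al <- lapply(seq_len(chains), function(ch)
      .chain_angle(loc$angle_rad, ind, pr, n_draws + n_warm, n_warm,
                   .substream(seed, 13L, ch)))
    list(d = dl, a = al)
  }
  res <- run(draws, warmup)
  rhat_of <- function(lst, col)
    split_rhat(sapply(lst, function(m) m[, col]))
  all_cols <- function(lst) colnames(lst[[1]])
  rhats <- c(vapply(all_cols(res$d), function(cc) rhat_of(res$d, cc), 0),
             vapply(all_cols(res$a), function(cc) rhat_of(res$a, cc), 0))
  hyper <- c("mu_d", "sigma_d", "tau_d", "mu_theta", "kappa", "tau_theta")
  if (max(rhats[hyper]) > 1.05 && on_nonconverged == "retry") {
    res <- run(draws * 2, warmup * 2)
    rhats <- c(vapply(all_cols(res$d), function(cc) rhat_of(res$d, cc), 0),
               vapply(all_cols(res$a), function(cc) rhat_of(res$a, cc), 0))
    on_nonconverged <- "error"
  }
  if (max(rhats[hyper]) > 1.05) {
    msg <- paste0("MCMC did not converge: max split-Rhat = ",
                  round(max(rhats[hyper]), 3), " (",
                  names(which.max(rhats[hyper])), ")")
    if (on_nonconverged == "error") stop(msg, call. = FALSE) else warning(msg)
  }
  D <- do.call(rbind, res$d)
  A <- do.call(rbind, res$a)
  chain <- rep(seq_len(chains), each = nrow(res$d[[1]]))
  ids <- attr(res$d[[1]], "ids")
  # derived observation-level spreads
  eff_sd_d <- sqrt(D[, "sigma_d"]^2 + D[, "tau_d"]^2)
  eff_sd_theta <- .eff_circ_sd_closed(A[, "kappa"], A[, "tau_theta"])
  post <- cbind(D[, c("mu_d", "sigma_d", "tau_d")], eff_sd_d = eff_sd_d,
                A[, c("mu_theta", "kappa", "tau_theta")],
                eff_sd_theta = eff_sd_theta, chain = chain)
  qs <- function(x) c(mean = mean(x), q2.5 = unname(stats::quantile(x, 0.025)),
                      q97.5 = unname(stats::quantile(x, 0.975)))
  ws <- .wrapped_summary(wrap_angle(A[, "mu_theta"]))
  summ <- rbind(
    mu_d = qs(post[, "mu_d"]), sigma_d = qs(post[, "sigma_d"]),
    tau_d = qs(post[, "tau_d"]), eff_sd_d = qs(post[, "eff_sd_d"]),
    mu_theta = ws, kappa = qs(post[, "kappa"]),
    tau_theta = qs(post[, "tau_theta"]),
    eff_sd_theta = qs(post[, "eff_sd_theta"]))
  summ <- as.data.frame(summ)
  structure(list(draws = post,
                 ranef = list(u = D[, grep("^u", colnames(D)), drop = FALSE],
                              v = A[, grep("^v", colnames(A)), drop = FALSE],
                              ids = ids),
                 summary = summ, rhat = rhats,
                 ess = c(mu_d = ess_basic(sapply(res$d, function(m) m[, "mu_d"])),
                         mu_theta = ess_basic(sapply(res$a, function(m) m[, "mu_theta"]))),
                 n_obs = nrow(loc), n_ind = length(unique(ind)),
                 chains = chains, group = group, priors = pr, seed = seed),
            class = "bat_hier")
}

#' @export
print.bat_hier <- function(x, ...) {
  g <- if (length(x$group)) paste0(" [", paste(unlist(x$group), collapse = ", "), "]") else ""
  cat(sprintf("<bat_hier>%s %d locations, %d individuals, %d chains\n",
              g, x$n_obs, x$n_ind, x$chains))
  s <- x$summary
  cat(sprintf("  distance: mean %.2f km [%.2f-%.2f], effective SD %.2f km, tau %.2f km\n",
              s["mu_d", "mean"], s["mu_d", "q2.5"], s["mu_d", "q97.5"],
              s["eff_sd_d", "mean"], s["tau_d", "mean"]))
  cat(sprintf("  bearing:  mean %.2f rad (%.1f deg) [%.2f-%.2f], effective SD %.2f rad, tau %.2f rad\n",
              s["mu_theta", "mean"], s["mu_theta", "mean"] * 180 / pi + 180,
              s["mu_theta", "q2.5"], s["mu_theta", "q97.5"],
              s["eff_sd_theta", "mean"], s["tau_theta", "mean"]))
  cat(sprintf("  max split-Rhat %.3f\n", max(x$rhat)))
  invisible(x)
}

#' @export
summary.bat_hier <- function(object, ...) {
  s <- object$summary
  s$compass_deg <- NA_real_
  s["mu_theta", "compass_deg"] <- s["mu_theta", "mean"] * 180 / pi + 180
  s
}

#' @export
coef.bat_hier <- function(object, ...) {
  stats::setNames(object$summary$mean, rownames(object$summary))
}

#' @export
confint.bat_hier <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  out <- t(apply(object$draws[, setdiff(colnames(object$draws), "chain")], 2,
                 stats::quantile, probs = c(a, 1 - a)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.bat_hier <- function(x, pars = c("mu_d", "mu_theta"), ...) {
  op <- graphics::par(mfrow = c(1, length(pars)))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::plot(stats::density(x$draws[, p]), main = p, xlab = p, ...)
  }
  invisible(x)
}

#' Posterior contrasts between two hierarchical fits
#'
#' Draw-wise differences (`a - b`) of the population means, effective SDs
#' and individual-level variabilities; the bearing mean difference is
#' wrapped to (-pi, pi]. Draw counts are truncated to the shorter fit with a
#' warning when they differ.
#'
#' @param fit_a,fit_b `bat_hier` fits sharing the parameterization.
#' @return data frame with posterior mean and central 95% interval per
#'   contrast.
#' @export
contrasts_hier <- function(fit_a, fit_b) {
  pa <- fit_a$draws; pb <- fit_b$draws
  n <- min(nrow(pa), nrow(pb))
  if (nrow(pa) != nrow(pb)) {
    warning("draw counts differ; truncating both to ", n)
    pa <- pa[seq_len(n), ]; pb <- pb[seq_len(n), ]
  }
  pars <- c("mu_d", "eff_sd_d", "tau_d", "mu_theta", "eff_sd_theta",
            "tau_theta", "kappa")
  rows <- lapply(pars, function(p) {
    dd <- if (p == "mu_theta") wrap_angle(pa[, p] - pb[, p]) else pa[, p] - pb[, p]
    data.frame(parameter = p, mean = mean(dd),
               q2.5 = unname(stats::quantile(dd, 0.025)),
               q97.5 = unname(stats::quantile(dd, 0.975)))
  })
  do.call(rbind, rows)
}
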