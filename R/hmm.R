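# Hidden Markov segmentation of regularized step series into behavioural
# states. Emissions: gamma step lengths and wrapped Cauchy turning angles;
# fitting by direct numerical maximization of the pooled forward
# log-likelihood (shared parameters across series, per-series initial
# distribution fixed to the stationary distribution of the transition
# matrix).

.stationary <- function(Gamma) {
  n <- nrow(Gamma)
  s <- try(solve(t(diag(n) - Gamma + 1), rep(1, n)), silent = TRUE)
  if (inherits(s, "try-error") || any(!is.finite(s)) || any(s < 0))
    s <- rep(1 / n, n)
  s / sum(s)
}

# observation matrix from a bat_steps series: one row per modelled slot
# (slots 1 .. n-1; the last grid slot carries no step), columns step/angle
.hmm_obs <- function(series) {
  n <- nrow(series)
  step <- series$step[seq_len(n - 1)]
  angle <- series$angle[seq_len(n - 1)]
  pos <- step[!is.na(step) & step > 0]
  if (any(!is.na(step) & step == 0)) {
    repl <- if (length(pos)) min(pos) / 2 else 1e-3
    step[!is.na(step) & step == 0] <- repl  # gamma density undefined at 0
  }
  cbind(step = step, angle = angle)
}

# log emission matrix (T x n_states); missing components contribute 0
.hmm_logE <- function(obs, shape, scale, mu, rho) {
  Tn <- nrow(obs); n <- length(shape)
  logE <- matrix(0, Tn, n)
  so <- !is.na(obs[, 1]); ao <- !is.na(obs[, 2])
  for (s in seq_len(n)) {
    if (any(so)) logE[so, s] <- stats::dgamma(obs[so, 1], shape = shape[s],
                                              scale = scale[s], log = TRUE)
    if (any(ao)) logE[ao, s] <- logE[ao, s] +
        dwrappedcauchy(obs[ao, 2], mu[s], rho[s], log = TRUE)
  }
  logE
}

#' Forward-algorithm log-likelihood of an HMM
#'
#' Missing observations contribute emission probability 1, i.e. a
#' transition-only step; the initial distribution is the model's `delta`.
#'
#' @param model a `bat_hmm` (or a bare parameter list with elements `shape`,
#'   `scale`, `mu`, `rho`, `Gamma`, `delta`).
#' @param series a `bat_steps` series from [regularize()].
#' @return log-likelihood (scalar).
#' @export
hmm_loglik <- function(model, series) {
  obs <- .hmm_obs(series)
  .forward_ll(.hmm_logE(obs, model$shape, model$scale, model$mu, model$rho),
              model$Gamma, model$delta)
}

.forward_ll <- function(logE, Gamma, delta) {
  Tn <- nrow(logE)
  if (Tn == 0) return(0)
  ll <- 0
  m <- max(logE[1, ])
  a <- delta * exp(logE[1, ] - m)
  s <- sum(a)
  ll <- ll + log(s) + m
  a <- a / s
  if (Tn > 1) for (t in 2:Tn) {
    m <- max(logE[t, ])
    a <- (a %*% Gamma)[1, ] * exp(logE[t, ] - m)
    s <- sum(a)
    if (s <= 0 || !is.finite(s)) return(-Inf)
    ll <- ll + log(s) + m
    a <- a / s
  }
  ll
}

# Pooled forward log-likelihood over several series, vectorized across
# series: all series are right-padded with missing observations (emission 1,
# transition-only steps leave the likelihood unchanged) and propagated as a
# single S x n matrix per time slot.
.forward_ll_pooled <- function(logE_arr, Gamma, delta) {
  S <- dim(logE_arr)[1]; n <- dim(logE_arr)[2]; Tn <- dim(logE_arr)[3]
  rowmax <- function(E) {
    m <- E[, 1]
    if (n > 1) for (s in 2:n) m <- pmax(m, E[, s])
    m
  }
  E1 <- matrix(logE_arr[, , 1], nrow = S)
  m <- rowmax(E1)
  A <- matrix(delta, S, n, byrow = TRUE) * exp(E1 - m)
  s <- rowSums(A)
  ll <- sum(log(s) + m)
  A <- A / s
  if (Tn > 1) for (t in 2:Tn) {
    Et <- matrix(logE_arr[, , t], nrow = S)
    m <- rowmax(Et)
    A <- (A %*% Gamma) * exp(Et - m)
    s <- rowSums(A)
    if (any(s <= 0) || any(!is.finite(s))) return(-Inf)
    ll <- ll + sum(log(s) + m)
    A <- A / s
  }
  ll
}

# stack observation matrices into a padded S x 2 x T array
.stack_obs <- function(obs_list) {
  Tn <- max(vapply(obs_list, nrow, 1L))
  S <- length(obs_list)
  arr <- array(NA_real_, c(S, 2, Tn))
  for (i in seq_len(S)) {
    o <- obs_list[[i]]
    arr[i, 1, seq_len(nrow(o))] <- o[, 1]
    arr[i, 2, seq_len(nrow(o))] <- o[, 2]
  }
  arr
}

# parameter vector <-> constrained parameters
.hmm_unpack <- function(par, n) {
  shape <- exp(par[seq_len(n)])
  scale <- exp(par[n + seq_len(n)])
  mu <- wrap_angle(par[2 * n + seq_len(n)])
  rho <- stats::plogis(par[3 * n + seq_len(n)])
  eta <- par[4 * n + seq_len(n * (n - 1))]
  Gamma <- diag(n)
  if (n > 1) {
    k <- 0
    for (i in seq_len(n)) {
      e <- exp(eta[k + seq_len(n - 1)]); k <- k + (n - 1)
      row <- numeric(n)
      row[-i] <- e / (1 + sum(e))
      row[i] <- 1 / (1 + sum(e))
      Gamma[i, ] <- row
    }
  }
  list(shape = shape, scale = scale, mu = mu, rho = rho, Gamma = Gamma,
       delta = .stationary(Gamma))
}

.hmm_pack <- function(shape, scale, mu, rho, Gamma) {
  n <- length(shape)
  eta <- numeric(0)
  if (n > 1) for (i in seq_len(n))
    eta <- c(eta, log(Gamma[i, -i] / Gamma[i, i]))
  c(log(shape), log(scale), mu, stats::qlogis(pmin(pmax(rho, 1e-4), 1 - 1e-4)), eta)
}

#' Fit an N-state movement HMM by pooled maximum likelihood
#'
#' Direct numerical optimization (Nelder-Mead) of the summed forward
#' log-likelihood over all supplied series, with log/logit transforms of the
#' constrained parameters and the best of `n_restarts` jittered
#' initializations. States are relabelled by increasing mean step length, so
#' state 1 is "foraging" (short, tortuous) and state `n_states` "commuting"
#' (long, straight).
#'
#' @param series_list a `bat_steps` series or list of them.
#' @param n_states number of behavioural states (default 2; 3-state models
#'   often score lower AIC but merge poorly interpretable sub-behaviours,
#'   and can be requested explicitly).
#' @param n_restarts random restarts.
#' @param seed integer seed controlling the restart jitter.
#' @param maxit optimizer iteration cap per restart.
#' @return an object of class `"bat_hmm"` with emission and transition
#'   parameters, `logLik`, `npar`, and `AIC`.
#' @export
fit_hmm <- function(series_list, n_states = 2, n_restarts = 3, seed = 1,
                    maxit = 1500) {
  if (inherits(series_list, "bat_steps")) series_list <- list(series_list)
  obs_list <- lapply(series_list, .hmm_obs)
  steps <- unlist(lapply(obs_list, function(o) o[!is.na(o[, 1]), 1]))
  if (length(steps) < 10)
    stop("need at least 10 non-missing steps to fit", call. = FALSE)
  if (stats::sd(steps) < 1e-9 || diff(range(steps)) < 1e-9)
    stop("degeneracy error: step lengths are constant; gamma scale would collapse",
         call. = FALSE)
  n <- n_states
  # data-driven starting values: cluster steps on the log scale, then
  # moment-match the gamma and circular parameters within each cluster
  angles <- unlist(lapply(obs_list, function(o) o[, 2]))[
    !is.na(unlist(lapply(obs_list, function(o) o[, 1])))]
  shape0 <- rep(1, n); scale0 <- rep(mean(steps), n)
  mu0 <- rep(0, n); rho0 <- seq(0.2, 0.8, length.out = n)
  cl <- if (n > 1) {
    km <- try(stats::kmeans(log(steps), centers = sort(
      stats::quantile(log(steps), probs = seq(0.15, 0.85, length.out = n)))),
      silent = TRUE)
    if (inherits(km, "try-error")) NULL else km$cluster
  } else rep(1L, length(steps))
  if (!is.null(cl)) {
    ord <- order(tapply(steps, cl, mean))
    for (k in seq_len(n)) {
      sk <- steps[cl == ord[k]]
      m1 <- mean(sk); s1 <- stats::sd(sk)
      if (is.finite(s1) && s1 > 0) {
        shape0[k] <- max(0.3, (m1 / s1)^2)
        scale0[k] <- s1^2 / m1
      } else scale0[k] <- max(m1, 1e-3)
      ak <- angles[cl == ord[k]]
      ak <- ak[!is.na(ak)]
      if (length(ak) > 5) {
        rho0[k] <- min(max(circ_R(ak), 0.05), 0.95)
        mu0[k] <- circ_mean(ak)
      }
    }
  }
  G0 <- matrix(0.2 / max(n - 1, 1), n, n); diag(G0) <- 0.8
  if (n == 1) G0 <- matrix(1, 1, 1)
  par0 <- .hmm_pack(shape0, scale0, mu0, rho0, G0)
  arr <- .stack_obs(obs_list)
  S <- dim(arr)[1]; Tn <- dim(arr)[3]
  step_v <- as.vector(arr[, 1, ]); angle_v <- as.vector(arr[, 2, ])
  so <- which(!is.na(step_v)); ao <- which(!is.na(angle_v))
  # index map from (series, slot) linear order into the (S, n, T) layout
  k_all <- seq_len(S * Tn)
  i_of <- (k_all - 1L) %% S + 1L
  t_of <- (k_all - 1L) %/% S
  tgt <- function(s) i_of + (s - 1L) * S + t_of * (S * n)
  tgt_idx <- lapply(seq_len(n), tgt)
  steps_obs <- step_v[so]; angles_obs <- angle_v[ao]
  nll <- function(par) {
    p <- .hmm_unpack(par, n)
    if (any(!is.finite(unlist(p[c("shape", "scale")])))) return(1e10)
    logE <- numeric(S * n * Tn)
    for (s in seq_len(n)) {
      ix <- tgt_idx[[s]]
      logE[ix[so]] <- stats::dgamma(steps_obs, shape = p$shape[s],
                                    scale = p$scale[s], log = TRUE)
      logE[ix[ao]] <- logE[ix[ao]] +
        dwrappedcauchy(angles_obs, p$mu[s], p$rho[s], log = TRUE)
    }
    dim(logE) <- c(S, n, Tn)
    ll <- .forward_ll_pooled(logE, p$Gamma, p$delta)
    if (!is.finite(ll)) 1e10 else -ll
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    par <- par0 + if (r == 1) 0 else stats::rnorm(length(par0), 0, 0.4)
    opt <- try(stats::optim(par, nll, method = "Nelder-Mead",
                            control = list(maxit = maxit)), silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    polish <- try(stats::optim(opt$par, nll, method = "BFGS",
                               control = list(maxit = 200)), silent = TRUE)
    if (!inherits(polish, "try-error") && is.finite(polish$value) &&
        polish$value < opt$value) opt <- polish
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit error: optimizer failed to converge on all restarts", call. = FALSE)
  p <- .hmm_unpack(best$par, n)
  ord <- order(p$shape * p$scale)  # label by mean step: 1 = foraging
  p$shape <- p$shape[ord]; p$scale <- p$scale[ord]
  p$mu <- p$mu[ord]; p$rho <- p$rho[ord]
  p$Gamma <- p$Gamma[ord, ord, drop = FALSE]
  p$delta <- .stationary(p$Gamma)
  npar <- 4 * n + n * (n - 1)
  ll <- -best$value
  structure(list(n_states = n, shape = p$shape, scale = p$scale,
                 mu = p$mu, rho = p$rho, Gamma = p$Gamma, delta = p$delta,
                 logLik = ll, npar = npar, AIC = 2 * npar - 2 * ll,
                 n_series = length(obs_list),
                 n_obs = sum(vapply(obs_list, nrow, 1L)),
                 convergence = best$convergence),
            class = "bat_hmm")
}

#' @export
print.bat_hmm <- function(x, ...) {
  cat(sprintf("<bat_hmm> %d-state movement HMM (%d series, %d slots)\n",
              x$n_states, x$n_series, x$n_obs))
  lab <- if (x$n_states == 2) c("foraging", "commuting")
         else paste0("state", seq_len(x$n_states))
  for (s in seq_len(x$n_states))
    cat(sprintf("  %-10s step ~ Gamma(shape=%.3g, scale=%.3g) [mean %.0f m]; turn ~ wC(mu=%.2f, rho=%.2f)\n",
                lab[s], x$shape[s], x$scale[s], x$shape[s] * x$scale[s],
                x$mu[s], x$rho[s]))
  cat(sprintf("  logLik %.2f, %d parameters, AIC %.2f\n", x$logLik, x$npar, x$AIC))
  invisible(x)
}

#' @export
logLik.bat_hmm <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.bat_hmm <- function(object, ...) {
  list(shape = object$shape, scale = object$scale, mu = object$mu,
       rho = object$rho, Gamma = object$Gamma, delta = object$delta)
}

#' @export
summary.bat_hmm <- function(object, ...) {
  print(object)
  cat("  transition matrix:\n")
  print(round(object$Gamma, 3))
  invisible(object)
}

#' Decode behavioural states
#'
#' Global decoding by the Viterbi algorithm plus forward-backward smoothing
#' probabilities. Slots with no observation take the state of the Viterbi
#' bridge and are flagged `imputed`; the final grid slot (which carries no
#' step) inherits the last decoded state.
#'
#' @param model a fitted `bat_hmm`.
#' @param series a `bat_steps` series.
#' @return a data frame, one row per grid slot of `series`: `state` (integer,
#'   1 = foraging), smoothing probabilities `p1..pn`, and `imputed`.
#' @export
decode_states <- function(model, series) {
  obs <- .hmm_obs(series)
  n <- model$n_states
  Tn <- nrow(obs)
  logE <- .hmm_logE(obs, model$shape, model$scale, model$mu, model$rho)
  lG <- log(model$Gamma)
  # Viterbi
  v <- matrix(-Inf, Tn, n); bp <- matrix(0L, Tn, n)
  v[1, ] <- log(model$delta) + logE[1, ]
  if (Tn > 1) for (t in 2:Tn) for (s in seq_len(n)) {
    cand <- v[t - 1, ] + lG[, s]
    bp[t, s] <- which.max(cand)
    v[t, s] <- cand[bp[t, s]] + logE[t, s]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(v[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- bp[t + 1, path[t + 1]]
  # forward-backward smoothing
  la <- matrix(0, Tn, n); lb <- matrix(0, Tn, n)
  a <- model$delta * exp(logE[1, ] - max(logE[1, ]))
  la[1, ] <- a / sum(a)
  if (Tn > 1) for (t in 2:Tn) {
    a <- (la[t - 1, ] %*% model$Gamma)[1, ] * exp(logE[t, ] - max(logE[t, ]))
    la[t, ] <- a / sum(a)
  }
  b <- rep(1, n)
  lb[Tn, ] <- b
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- (model$Gamma %*% (exp(logE[t + 1, ] - max(logE[t + 1, ])) * b))[, 1]
    b <- b / sum(b)
    lb[t, ] <- b
  }
  post <- la * lb
  post <- post / rowSums(post)
  no_obs <- apply(is.na(obs), 1, all)
  out <- data.frame(state = c(path, path[Tn]))
  pm <- rbind(post, post[Tn, , drop = FALSE])
  colnames(pm) <- paste0("p", seq_len(n))
  out <- cbind(out, as.data.frame(pm))
  out$imputed <- c(no_obs, TRUE)
  out
}
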