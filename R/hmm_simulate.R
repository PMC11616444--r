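# Emission-level simulation from an HMM: a Markov state chain with gamma
# steps and wrapped Cauchy turns, materialized as a regular step series.
# Used for parameter-recovery checks and as the engine under the
# landscape-constrained null-track simulator.

#' Simulate a step series from an HMM
#'
#' Draws a state chain from the transition matrix (initial state from
#' `delta`), then step lengths and turning angles from the state's emission
#' distributions, and integrates them into planar positions (initial heading
#' uniform). The true state chain is attached as attribute `"truth_states"`.
#'
#' @param model a `bat_hmm`, or a [movement_kernel()] (fields are shared).
#' @param n_slots number of grid slots (the series carries `n_slots - 1` steps).
#' @param seed integer seed.
#' @param start `c(x, y)` starting position (m).
#' @param interval grid interval (s), for the time axis only.
#' @return a `bat_steps` data frame as produced by [regularize()].
#' @export
simulate_steps <- function(model, n_slots = 360, seed = 1, start = c(0, 0),
                           interval = 120) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n <- length(model$shape)
  delta <- model$delta %||% .stationary(model$Gamma)
  ns <- n_slots - 1L  # number of steps
  st <- integer(ns)
  st[1] <- sample(seq_len(n), 1, prob = delta)
  for (t in seq_len(ns - 1L))
    st[t + 1L] <- sample(seq_len(n), 1, prob = model$Gamma[st[t], ])
  steps <- stats::rgamma(ns, shape = model$shape[st], scale = model$scale[st])
  turns <- numeric(ns)
  for (t in 2:ns) turns[t] <- rwrappedcauchy(1, model$mu[st[t]], model$rho[st[t]])
  heading <- cumsum(c(stats::runif(1, -pi, pi), turns[-1]))
  x <- start[1] + cumsum(c(0, steps * cos(heading)))
  y <- start[2] + cumsum(c(0, steps * sin(heading)))
  t0 <- as.POSIXct("2022-03-01 23:00:00", tz = "UTC") +
    (seq_len(n_slots) - 1L) * interval
  df <- data.frame(time = t0, x = x, y = y, obs = TRUE,
                   step = c(steps, NA_real_),
                   angle = c(NA_real_, turns[-1], NA_real_))
  out <- structure(df, interval = interval,
                   track_meta = list(individual_id = "sim", colony_id = "sim",
                                     season = NA, period = NA, night_date = NA),
                   class = c("bat_steps", "data.frame"))
  attr(out, "truth_states") <- c(st, st[ns])
  out
}

#' @param object a fitted `bat_hmm`.
#' @param nsim number of series to simulate.
#' @param seed integer seed (substreamed per series).
#' @param ... passed to [simulate_steps()].
#' @rdname simulate_steps
#' @export
simulate.bat_hmm <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_steps(object, seed = .substream(seed, i), ...))
}
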