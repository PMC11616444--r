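# Circular distributions and summaries used throughout the pipeline.
# Angles are radians; the working range is (-pi, pi].

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi  # %% maps the seam to -pi; convention puts it at +pi
  w
}

#' Wrapped Cauchy density
#'
#' Density of the wrapped Cauchy distribution with location `mu` and
#' concentration `rho`: (1/2pi) (1 - rho^2) / (1 + rho^2 - 2 rho cos(x - mu)).
#' `rho = 0` is the circular uniform; `rho -> 1` concentrates at `mu`.
#'
#' @param x angles (radians).
#' @param mu location (radians).
#' @param rho concentration in `[0, 1)`.
#' @param log return log-density?
#' @return density values.
#' @export
dwrappedcauchy <- function(x, mu = 0, rho = 0, log = FALSE) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  d <- (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(x - mu)))
  if (log) base::log(d) else d
}

#' Wrapped Cauchy random deviates
#'
#' @param n number of draws.
#' @inheritParams dwrappedcauchy
#' @return `n` angles in (-pi, pi].
#' @export
rwrappedcauchy <- function(n, mu = 0, rho = 0) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (rho == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  # wrapping a Cauchy with scale -log(rho) yields concentration rho
  wrap_angle(mu + stats::rcauchy(n, location = 0, scale = -base::log(rho)))
}

#' von Mises density
#'
#' Uses exponentially scaled Bessel I0 for stability at large `kappa`.
#'
#' @param x angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (> 0; `kappa = 0` is uniform).
#' @param log return log-density?
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  ld <- kappa * (cos(x - mu) - 1) - base::log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' von Mises random deviates (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @inheritParams dvonmises
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || base::log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(mu + out)
}

#' Circular mean, resultant length and standard deviation
#'
#' Circular SD is `sqrt(-2 log Rbar)` with `Rbar` the mean resultant length.
#'
#' @param x angles (radians); `NA` removed.
#' @return `circ_mean`: mean direction in (-pi, pi]; `circ_R`: mean resultant
#'   length in `[0, 1]`; `circ_sd`: circular standard deviation (radians).
#' @export
circ_mean <- function(x) {
  x <- x[!is.na(x)]
  atan2(mean(sin(x)), mean(cos(x)))
}

#' @rdname circ_mean
#' @export
circ_R <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean(sin(x))^2 + mean(cos(x))^2)
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x) {
  R <- circ_R(x)
  sqrt(-2 * base::log(max(R, .Machine$double.xmin)))
}
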