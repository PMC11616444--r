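# Landscape-constrained null-track simulation: generative sampling from a
# fitted movement HMM, representing where bats *could* have foraged given
# the landscape but no resource information. The procedure is a
# reconstruction (generative kernel + rejection constraints + a return-bias
# schedule); every choice is exposed as an argument.

#' Simulate one landscape-constrained null track
#'
#' Samples a state chain from the kernel's transition matrix and step/turn
#' emissions from its state distributions, subject to: (a) transitions into
#' the foraging state are rejected while the current position is over water
#' (the chain stays commuting); (b) headings evolve by wrapped Cauchy turns
#' around the previous heading, with the initial heading uniform; (c) after
#' `return_onset` of the night the commuting-state heading is re-centred on
#' the bearing to the roost; (d) positions outside the bounding box trigger
#' heading resampling (up to 100 attempts, then reflection).
#'
#' @param kernel a fitted `bat_hmm` (or [movement_kernel()]).
#' @param roost `c(x, y)` start position (m).
#' @param ls a [landscape()].
#' @param n_slots,interval night grid (defaults: a full 12 h night at 120 s).
#' @param seed integer seed.
#' @param return_onset fraction of the night after which commuting headings
#'   are biased back towards the roost.
#' @param bbox bounding box `c(xmin, xmax, ymin, ymax)` (m); default the
#'   landscape box padded by 5 km.
#' @return a `bat_steps` series with attribute `"truth_states"`.
#' @export
simulate_null_track <- function(kernel, roost, ls, n_slots = 360,
                                interval = 120, seed = 1,
                                return_onset = 0.5, bbox = NULL) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (is.null(bbox))
    bbox <- ls$bbox + c(-5000, 5000, -5000, 5000)
  n <- length(kernel$shape)
  delta <- kernel$delta %||% .stationary(kernel$Gamma)
  commuting <- n  # states labelled by increasing mean step
  st <- integer(n_slots); x <- numeric(n_slots); y <- numeric(n_slots)
  x[1] <- roost[1]; y[1] <- roost[2]
  st[1] <- sample(seq_len(n), 1, prob = delta)
  heading <- stats::runif(1, -pi, pi)
  for (t in 2:n_slots) {
    s_prop <- sample(seq_len(n), 1, prob = kernel$Gamma[st[t - 1], ])
    # (a) no foraging over water: stay commuting instead
    if (s_prop < commuting && !is_on_land(x[t - 1], y[t - 1], ls))
      s_prop <- commuting
    st[t] <- s_prop
    step <- stats::rgamma(1, shape = kernel$shape[s_prop],
                          scale = kernel$scale[s_prop])
    base_heading <- if (s_prop == commuting && t > return_onset * n_slots)
      atan2(roost[2] - y[t - 1], roost[1] - x[t - 1])  # (c) return bias
    else heading
    ok <- FALSE
    for (try in 1:100) {
      h <- base_heading + rwrappedcauchy(1, kernel$mu[s_prop], kernel$rho[s_prop])
      xn <- x[t - 1] + step * cos(h)
      yn <- y[t - 1] + step * sin(h)
      if (xn >= bbox[1] && xn <= bbox[2] && yn >= bbox[3] && yn <= bbox[4]) {
        ok <- TRUE; break
      }
      if (try >= 100) break
      # re-draw the heading; after repeated failures aim inward
      if (try > 10) base_heading <- atan2(mean(bbox[3:4]) - y[t - 1],
                                          mean(bbox[1:2]) - x[t - 1])
    }
    if (!ok) {  # (d) reflect back inside
      xn <- pmin(pmax(xn, bbox[1]), bbox[2])
      yn <- pmin(pmax(yn, bbox[3]), bbox[4])
      h <- atan2(yn - y[t - 1], xn - x[t - 1])
    }
    x[t] <- xn; y[t] <- yn; heading <- h
  }
  t0 <- as.POSIXct("2022-03-01 23:00:00", tz = "UTC") +
    (seq_len(n_slots) - 1L) * interval
  steps <- c(sqrt(diff(x)^2 + diff(y)^2), NA_real_)
  hd <- atan2(diff(y), diff(x))
  ang <- rep(NA_real_, n_slots)
  if (n_slots >= 3)
    ang[2:(n_slots - 1)] <- wrap_angle(hd[-1] - hd[-length(hd)])
  out <- structure(
    data.frame(time = t0, x = x, y = y, obs = TRUE, step = steps, angle = ang),
    interval = interval,
    track_meta = list(individual_id = "null", colony_id = NA, season = NA,
                      period = NA, night_date = NA),
    class = c("bat_steps", "data.frame"))
  attr(out, "truth_states") <- st
  out
}

#' Simulate a null cohort and extract its foraging locations
#'
#' Each observed template night spawns `n_per_template` null tracks from the
#' pooled kernel of its colony-season; foraging locations are extracted with
#' the *same* [extract_foraging_locations()] code path as observed data, and
#' locations over water are dropped (drop rate in attribute
#' `"water_drop_rate"`).
#'
#' @param templates data frame with one row per observed night: columns
#'   `colony_id`, `season`, `individual_id`, `n_slots`, `interval`.
#' @param kernel pooled `bat_hmm` for this colony-season.
#' @param ls a [landscape()].
#' @param n_per_template replicates per template night.
#' @param seed integer master seed (substreamed per template x replicate).
#' @param ... passed on to [simulate_null_track()].
#' @return a foraging-location data frame with `provenance = "simulated"`.
#' @export
simulate_null_cohort <- function(templates, kernel, ls, n_per_template = 5,
                                 seed = 1, ...) {
  rows <- list(); n_total <- 0L; n_water <- 0L
  for (i in seq_len(nrow(templates))) {
    tpl <- templates[i, ]
    roost <- ls$roosts[[tpl$colony_id]]
    if (is.null(roost)) stop("unknown colony_id: ", tpl$colony_id, call. = FALSE)
    for (r in seq_len(n_per_template)) {
      ser <- simulate_null_track(kernel, roost, ls,
                                 n_slots = tpl$n_slots %||% 360,
                                 interval = tpl$interval %||% 120,
                                 seed = .substream(seed, i, r), ...)
      states <- data.frame(state = attr(ser, "truth_states"))
      fl <- extract_foraging_locations(
        ser, states, roost, ls,
        meta = list(individual_id = tpl$individual_id,
                    colony_id = tpl$colony_id, season = tpl$season,
                    provenance = "simulated", template = i, replicate = r))
      if (!nrow(fl)) next
      n_total <- n_total + nrow(fl)
      wet <- !is_on_land(fl$x, fl$y, ls)
      n_water <- n_water + sum(wet)
      fl <- fl[!wet, , drop = FALSE]  # exclude foraging that fell on water
      if (nrow(fl)) rows[[length(rows) + 1L]] <- fl
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  attr(out, "water_drop_rate") <- if (n_total) n_water / n_total else NA_real_
  out
}
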