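# Synthetic study generator: colony scenarios, movement kernels, and
# bat-night track simulation with ground truth. Emulates the statistical
# structure of nightly central-place foraging trips: a fast straight
# outbound commute to a colony-specific distant foraging area, alternating
# foraging bouts and short relocations there, and a straight inbound
# commute; optional GPS corruptions (dropout, speed spikes, over-water
# strays).

#' Movement kernel: two-state step/turn emission model
#'
#' State 1 is foraging (short tortuous steps), state 2 commuting (long
#' straight steps). Step lengths are gamma-distributed displacements per
#' sampling interval (metres); turning angles are wrapped Cauchy. Defaults
#' give a ~1 m/s foraging and ~10 m/s commuting speed at a 120 s interval,
#' below the 15 m/s biological plausibility filter.
#'
#' @param shape,scale gamma parameters per state (length 2).
#' @param mu,rho wrapped Cauchy turning-angle parameters per state.
#' @param Gamma 2x2 transition matrix (rows sum to 1).
#' @param interval sampling interval (s) the step scale refers to.
#' @export
movement_kernel <- function(shape = c(1.5, 50), scale = c(80, 24),
                            mu = c(0, 0), rho = c(0.2, 0.95),
                            Gamma = rbind(c(0.90, 0.10), c(0.15, 0.85)),
                            interval = 120) {
  stopifnot(all(shape > 0), all(scale > 0), all(rho >= 0 & rho < 1),
            all(abs(rowSums(Gamma) - 1) < 1e-10))
  structure(list(shape = shape, scale = scale, mu = mu, rho = rho,
                 Gamma = Gamma, interval = interval),
            class = "bat_kernel")
}

#' Colony scenario: the generative conditions for one colony-season
#'
#' Defaults reflect the study system: commutes of 15-25 km to
#' colony-specific mainland foraging areas, tight bearings in the dry
#' season, roughly doubled angular spread in the wet season, and about 30%
#' of foraging time spent on the home island.
#'
#' @param colony_id colony label (must match a landscape roost).
#' @param season `"dry"` or `"wet"`.
#' @param n_individuals,nights_per_individual cohort size.
#' @param mean_commute_distance population mean distance to the foraging
#'   area (km).
#' @param commute_angle_mean population mean bearing (radians; 0 = due
#'   south, positive clockwise).
#' @param commute_angle_sd night-to-night angular spread (rad).
#' @param individual_angle_sd between-individual spread of mean bearing (rad).
#' @param individual_distance_sd between-individual spread of mean
#'   distance (km).
#' @param night_distance_sd night-to-night distance spread (km).
#' @param p_on_island_foraging fraction of foraging time on the home island.
#' @export
colony_scenario <- function(colony_id = "colony1", season = c("dry", "wet"),
                            n_individuals = 5, nights_per_individual = 4,
                            mean_commute_distance = 22,
                            commute_angle_mean = 1.2,
                            commute_angle_sd = if (season == "dry") 0.15 else 0.30,
                            individual_angle_sd = if (season == "dry") 0.12 else 0.25,
                            individual_distance_sd = 2,
                            night_distance_sd = 1,
                            p_on_island_foraging = 0.3) {
  season <- match.arg(season)
  stopifnot(mean_commute_distance > 0, commute_angle_sd >= 0,
            individual_angle_sd >= 0, individual_distance_sd >= 0,
            p_on_island_foraging >= 0, p_on_island_foraging <= 1)
  structure(list(colony_id = colony_id, season = season,
                 n_individuals = n_individuals,
                 nights_per_individual = nights_per_individual,
                 mean_commute_distance = mean_commute_distance,
                 commute_angle_mean = commute_angle_mean,
                 commute_angle_sd = commute_angle_sd,
                 individual_angle_sd = individual_angle_sd,
                 individual_distance_sd = individual_distance_sd,
                 night_distance_sd = night_distance_sd,
                 p_on_island_foraging = p_on_island_foraging),
            class = "bat_scenario")
}

# deterministic substream seed from a base seed and integer indices
.substream <- function(seed, ...) {
  ix <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in seq_along(ix))
    s <- (s * 48271 + as.numeric(ix[k]) * 16807 + k) %% 2147483647
  as.integer(s)
}

# unit displacement for a bearing in the south-zero clockwise convention
.bearing_to_unit <- function(theta) cbind(-sin(theta), -cos(theta))

# bearing (south-zero clockwise) of the vector from `from` to `to`
.bearing_of <- function(from, to) {
  atan2(-(to[1] - from[1]), -(to[2] - from[2]))
}

# draw a commuting/foraging step, capped so implied speed stays plausible
.step_draw <- function(kernel, state, cap) {
  min(stats::rgamma(1, shape = kernel$shape[state], scale = kernel$scale[state]), cap)
}

# biased correlated walk from `pos` towards `target`; returns matrix of
# positions (one row per slot) and stops within `capture` of the target
.commute_walk <- function(pos, target, kernel, max_slots, bias = 0.8,
                          capture = 800, max_speed = 15) {
  cap <- 0.95 * max_speed * kernel$interval
  out <- matrix(NA_real_, max_slots, 2)
  heading <- atan2(target[2] - pos[2], target[1] - pos[1])  # math convention
  for (t in seq_len(max_slots)) {
    to_target <- atan2(target[2] - pos[2], target[1] - pos[1])
    # circular convex combination of current heading and target direction
    heading <- atan2((1 - bias) * sin(heading) + bias * sin(to_target),
                     (1 - bias) * cos(heading) + bias * cos(to_target))
    # commuting turn noise, truncated: directed flight has no hairpin turns
    for (try in 1:20) {
      turn <- rwrappedcauchy(1, kernel$mu[2], kernel$rho[2])
      if (abs(turn) < pi / 3) break
    }
    heading <- heading + turn
    step <- .step_draw(kernel, 2L, cap)
    d2t <- sqrt(sum((target - pos)^2))
    if (step >= d2t) {  # arrive exactly rather than overshoot
      pos <- target + stats::rnorm(2, 0, 30)
      out[t, ] <- pos
      return(list(pos = out[seq_len(t), , drop = FALSE], arrived = TRUE))
    }
    pos <- pos + step * c(cos(heading), sin(heading))
    out[t, ] <- pos
    if (sqrt(sum((target - pos)^2)) <= capture)
      return(list(pos = out[seq_len(t), , drop = FALSE], arrived = TRUE))
  }
  list(pos = out, arrived = FALSE)
}

# foraging-phase walk: two-state Markov chain around an anchor with a soft
# leash; returns positions and states
.foraging_walk <- function(pos, anchor, kernel, n_slots, leash = 1500,
                           max_speed = 15) {
  cap <- 0.95 * max_speed * kernel$interval
  ps <- matrix(NA_real_, n_slots, 2)
  st <- integer(n_slots)
  state <- 1L
  heading <- stats::runif(1, -pi, pi)
  for (t in seq_len(n_slots)) {
    state <- sample(1:2, 1, prob = kernel$Gamma[state, ])
    heading <- heading + rwrappedcauchy(1, kernel$mu[state], kernel$rho[state])
    dist_a <- sqrt(sum((anchor - pos)^2))
    if (dist_a > leash)  # drift back towards the anchor
      heading <- atan2(anchor[2] - pos[2], anchor[1] - pos[1]) +
        rwrappedcauchy(1, 0, 0.5)
    step <- .step_draw(kernel, state, if (state == 2L) min(cap, 600) else cap)
    pos <- pos + step * c(cos(heading), sin(heading))
    ps[t, ] <- pos
    st[t] <- state
  }
  list(pos = ps, states = st)
}

#' Simulate one bat-night
#'
#' Generates a full 18:00-06:00 track at the kernel's sampling interval: an
#' optional on-island foraging bout near the roost, an outbound commute to
#' an individual-specific off-island anchor, alternating foraging/relocation
#' behaviour there, an inbound commute, and roosting until 06:00. The true
#' behavioural state of every slot (1 = foraging, 2 = commuting) is attached
#' as attribute `"truth"` together with the night's anchor, bearing and
#' distance.
#'
#' @param scenario a [colony_scenario()].
#' @param kernel a [movement_kernel()].
#' @param individual_effects list with `angle_mean` (rad) and
#'   `distance_mean` (km) for this bat, and its `individual_id`.
#' @param seed integer seed for this night's substream.
#' @param ls a [landscape()]; the foraging anchor must fall on land.
#' @param night_date local date of the 18:00 start.
#' @param corruptions list: `dropout` (per-fix probability), `speed_spikes`
#'   and `water_strays` (counts of injected outlier fixes).
#' @param tz local timezone.
#' @return a `bat_track` with truth attributes.
#' @export
simulate_night <- function(scenario, kernel, individual_effects, seed, ls,
                           night_date = as.Date("2022-03-01"),
                           corruptions = list(dropout = 0, speed_spikes = 0,
                                              water_strays = 0),
                           tz = "America/Panama") {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  roost <- ls$roosts[[scenario$colony_id]]
  if (is.null(roost)) stop("unknown colony_id: ", scenario$colony_id, call. = FALSE)
  interval <- kernel$interval
  n_slots <- as.integer(12 * 3600 / interval)

  # night-level target: bearing and distance with anchor-on-land rejection
  anchor <- NULL
  for (try in 1:200) {
    bearing <- wrap_angle(individual_effects$angle_mean +
                            stats::rnorm(1, 0, scenario$commute_angle_sd))
    dist_km <- max(2, individual_effects$distance_mean +
                     stats::rnorm(1, 0, scenario$night_distance_sd))
    cand <- roost + dist_km * 1000 * .bearing_to_unit(bearing)[1, ]
    if (is_on_land(cand[1], cand[2], ls) &&
        !is_on_home_island(cand[1], cand[2], ls)) { anchor <- cand; break }
  }
  if (is.null(anchor))
    stop("generation error: foraging target falls over water for colony ",
         scenario$colony_id, call. = FALSE)

  pos_list <- list(); state_list <- list()
  pos <- roost + stats::rnorm(2, 0, 20)
  pos_list[[1]] <- matrix(pos, 1); state_list[[1]] <- 1L

  commute_slots_est <- ceiling(dist_km * 1000 /
                                 (kernel$shape[2] * kernel$scale[2])) + 4
  budget <- n_slots - 2 * commute_slots_est - 8
  forage_total <- max(20, budget)
  on_slots <- round(scenario$p_on_island_foraging * forage_total)
  off_slots <- forage_total - on_slots

  out_c <- .commute_walk(pos, anchor, kernel, max_slots = 3 * commute_slots_est)
  pos_list[[length(pos_list) + 1L]] <- out_c$pos
  state_list[[length(state_list) + 1L]] <- rep(2L, nrow(out_c$pos))
  pos <- out_c$pos[nrow(out_c$pos), ]

  used <- sum(vapply(pos_list, nrow, 1L))
  # budget the inbound leg from the realized outbound length so the night
  # ends at the roost with minimal slack
  off_slots <- max(10, min(off_slots,
                           n_slots - used - nrow(out_c$pos) - on_slots - 10))
  fw <- .foraging_walk(pos, anchor, kernel, off_slots)
  pos_list[[length(pos_list) + 1L]] <- fw$pos
  state_list[[length(state_list) + 1L]] <- fw$states
  pos <- fw$pos[nrow(fw$pos), ]

  in_c <- .commute_walk(pos, roost, kernel, max_slots = 3 * commute_slots_est,
                        capture = 200)
  pos_list[[length(pos_list) + 1L]] <- in_c$pos
  state_list[[length(state_list) + 1L]] <- rep(2L, nrow(in_c$pos))
  pos <- in_c$pos[nrow(in_c$pos), ]

  used <- sum(vapply(pos_list, nrow, 1L))
  on_slots <- min(on_slots, n_slots - used - 8)
  if (on_slots > 0) {  # on-island foraging near the roost after the return
    on_anchor <- NULL
    for (try in 1:100) {
      th <- stats::runif(1, -pi, pi)
      rr <- stats::runif(1, 400, 1500)
      cand <- roost + rr * c(cos(th), sin(th))
      if (is_on_home_island(cand[1], cand[2], ls)) { on_anchor <- cand; break }
    }
    if (is.null(on_anchor)) on_anchor <- roost
    fw <- .foraging_walk(pos, on_anchor, kernel, on_slots, leash = 800)
    pos_list[[length(pos_list) + 1L]] <- fw$pos
    state_list[[length(state_list) + 1L]] <- fw$states
    pos <- fw$pos[nrow(fw$pos), ]
    # short hop home so the roosting slots do not imply a speed jump
    back <- .commute_walk(pos, roost, kernel, max_slots = 6, capture = 150)
    pos_list[[length(pos_list) + 1L]] <- back$pos
    state_list[[length(state_list) + 1L]] <- rep(2L, nrow(back$pos))
  }

  P <- do.call(rbind, pos_list)
  S <- c(unlist(state_list))
  if (nrow(P) < n_slots) {  # roosting until 06:00: tiny movements at the cave
    k <- n_slots - nrow(P)
    roost_jit <- matrix(rep(roost, each = k), k) + matrix(stats::rnorm(2 * k, 0, 10), k)
    P <- rbind(P, roost_jit)
    S <- c(S, rep(1L, k))
  } else { P <- P[seq_len(n_slots), , drop = FALSE]; S <- S[seq_len(n_slots)] }

  start <- as.POSIXct(paste(format(night_date), "18:00:00"), tz = tz)
  times <- start + (seq_len(n_slots) - 1L) * interval
  keep <- rep(TRUE, n_slots)
  spike_idx <- integer(0); stray_idx <- integer(0)
  nsp <- corruptions$speed_spikes %||% 0
  nst <- corruptions$water_strays %||% 0
  if (nsp + nst > 0) {
    # corruption fixes model isolated receiver glitches: keep them at least
    # three slots apart so removals cannot cascade into clean fixes
    picked <- integer(0)
    cand <- 3:(n_slots - 2)
    for (k in seq_len(nsp + nst)) {
      ok <- cand[!cand %in% unlist(lapply(picked, function(p) (p - 2):(p + 2)))]
      if (!length(ok)) break
      picked <- c(picked, sample(ok, 1))
    }
    spike_idx <- sort(picked[seq_len(min(nsp, length(picked)))])
    stray_idx <- sort(picked[setdiff(seq_along(picked), seq_len(nsp))])
  }
  if (length(spike_idx)) {
    th <- stats::runif(length(spike_idx), -pi, pi)
    P[spike_idx, ] <- P[spike_idx, ] +
      stats::runif(length(spike_idx), 5000, 8000) * cbind(cos(th), sin(th))
  }
  if (length(stray_idx)) {
    th <- stats::runif(length(stray_idx), -pi, pi)
    P[stray_idx, ] <- matrix(rep(roost, each = length(stray_idx)),
                             length(stray_idx)) +
      70000 * cbind(cos(th), sin(th))  # far over open water
  }
  dp <- corruptions$dropout %||% 0
  if (dp > 0) {
    interior <- 2:(n_slots - 1)
    keep[interior] <- stats::runif(length(interior)) >= dp
    keep[c(spike_idx, stray_idx)] <- TRUE  # corruption fixes always present
  }

  ll <- unproject_xy(P[, 1], P[, 2], ls$crs)
  fixes <- data.frame(time = times, lon = ll[, 1], lat = ll[, 2],
                      x = P[, 1], y = P[, 2])[keep, ]
  rownames(fixes) <- NULL
  fixes$speed <- .track_speeds(fixes)
  tr <- new_track(individual_effects$individual_id %||% "sim",
                  scenario$colony_id, scenario$season,
                  format(night_date, "%Y-%m"), night_date, fixes,
                  interval = interval)
  attr(tr, "truth") <- list(
    states = S[keep], states_full = S, kept = keep,
    anchor = anchor, bearing = bearing, distance_km = dist_km,
    spike_times = times[spike_idx], stray_times = times[stray_idx])
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-colony tracking study with ground truth
#'
#' Draws per-individual mean bearings and distances from each scenario's
#' between-individual distributions, then simulates every bat-night through
#' [simulate_night()]. All randomness flows from `seed` via per-(colony,
#' individual, night) substreams, so the result is reproducible and
#' insensitive to evaluation order.
#'
#' @param scenarios list of [colony_scenario()] objects.
#' @param kernel a [movement_kernel()].
#' @param ls a [landscape()].
#' @param seed integer master seed.
#' @param start_date first night's local date.
#' @param corruptions passed to [simulate_night()].
#' @return list with `tracks` (list of `bat_track`), and `truth`: data frames
#'   `individuals` (true per-individual angle/distance means) and `nights`
#'   (per-night anchors, bearings, distances).
#' @export
simulate_dataset <- function(scenarios, kernel = movement_kernel(), ls,
                             seed = 1, start_date = as.Date("2022-03-01"),
                             corruptions = list(dropout = 0, speed_spikes = 0,
                                                water_strays = 0)) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  tracks <- list()
  ind_rows <- list(); night_rows <- list()
  for (ci in seq_along(scenarios)) {
    sc <- scenarios[[ci]]
    set.seed(.substream(seed, 1L, ci))
    ang <- wrap_angle(sc$commute_angle_mean +
                        stats::rnorm(sc$n_individuals, 0, sc$individual_angle_sd))
    dst <- sc$mean_commute_distance +
      stats::rnorm(sc$n_individuals, 0, sc$individual_distance_sd)
    for (ii in seq_len(sc$n_individuals)) {
      iid <- sprintf("%s_b%02d", sc$colony_id, ii)
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        individual_id = iid, colony_id = sc$colony_id, season = sc$season,
        true_angle_mean = ang[ii], true_distance_mean = dst[ii])
      eff <- list(individual_id = iid, angle_mean = ang[ii],
                  distance_mean = dst[ii])
      for (ni in seq_len(sc$nights_per_individual)) {
        tr <- simulate_night(sc, kernel, eff,
                             seed = .substream(seed, 2L, ci, ii, ni),
                             ls = ls, night_date = start_date + (ni - 1L),
                             corruptions = corruptions)
        tru <- attr(tr, "truth")
        night_rows[[length(night_rows) + 1L]] <- data.frame(
          individual_id = iid, colony_id = sc$colony_id, season = sc$season,
          night_date = format(start_date + (ni - 1L)),
          anchor_x = tru$anchor[1], anchor_y = tru$anchor[2],
          bearing = tru$bearing, distance_km = tru$distance_km)
        tracks[[length(tracks) + 1L]] <- tr
      }
    }
  }
  list(tracks = tracks,
       truth = list(individuals = do.call(rbind, ind_rows),
                    nights = do.call(rbind, night_rows)))
}
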