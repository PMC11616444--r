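# Foraging metrics: commute straightness, foraging-location extraction,
# distance/bearing to the roost, on/off-island foraging-time proportions
# with binomial GLMs, and the nectar-tree energetics utility.
#
# Bearing convention (used everywhere): radians with 0 = due south,
# positive clockwise, range (-pi, pi]; compass degrees = rad * 180/pi + 180.

#' Distance and bearing from the roost
#'
#' @param x,y projected coordinates (m), vectorized.
#' @param roost `c(x, y)` roost coordinates (m).
#' @return data frame with `distance_km`, `angle_rad` (south-zero,
#'   clockwise-positive) and `compass_deg` (`angle_rad * 180/pi + 180`).
#' @export
angle_distance_to_roost <- function(x, y, roost) {
  dx <- x - roost[1]; dy <- y - roost[2]
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0))
    stop("angle undefined: point coincides with the roost", call. = FALSE)
  ang <- wrap_angle(atan2(-dx, -dy))
  data.frame(distance_km = d / 1000, angle_rad = ang,
             compass_deg = ang * 180 / pi + 180)
}

# maximal runs of a given state; returns data.frame(start, end, length)
.state_runs <- function(states, value) {
  r <- rle(states == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Straightness index of a path
#'
#' Net displacement divided by cumulative path length: 1 = perfectly
#' straight, 0 = closed loop.
#'
#' @param x,y coordinates of the path vertices, in order.
#' @export
straightness_index <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path == 0) return(NA_real_)
  sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2) / path
}

#' Extract commute segments and their straightness indices
#'
#' The outbound commute is the maximal run of commuting-state slots between
#' the first departure from the roost radius and the first subsequent
#' foraging bout; the inbound commute is its mirror image at the end of the
#' night. With `full_path = TRUE` the segment instead spans from the roost
#' departure to the first foraging slot regardless of decoded state.
#'
#' @param series a `bat_steps` series.
#' @param states decode result from [decode_states()] (rows align with
#'   `series`).
#' @param roost `c(x, y)` (m).
#' @param roost_radius_m radius defining "at the roost".
#' @param full_path use the roost-to-first-foraging path instead of the
#'   commuting-state run.
#' @return data frame with one row per commute: `direction`, `start`, `end`
#'   (slot indices), `straightness`.
#' @export
extract_commutes <- function(series, states, roost, roost_radius_m = 500,
                             full_path = FALSE) {
  st <- states$state
  n <- nrow(series)
  d <- sqrt((series$x - roost[1])^2 + (series$y - roost[2])^2)
  commuting <- max(st)  # highest-step state label
  out <- list()
  dep <- which(!is.na(d) & d > roost_radius_m)[1]
  if (!is.na(dep)) {
    # first foraging bout after departure (ignore singleton foraging slots)
    fb <- .state_runs(st, 1L)
    fb <- fb[fb$start > dep & fb$length > 1, , drop = FALSE]
    stop_at <- if (nrow(fb)) fb$start[1] else n
    seg <- if (full_path) dep:stop_at else {
      cr <- .state_runs(st[seq_len(stop_at)], commuting)
      cr <- cr[cr$end >= dep, , drop = FALSE]
      if (nrow(cr)) cr$start[1]:cr$end[nrow(cr)] else integer(0)
    }
    if (length(seg) >= 2)
      out[[length(out) + 1L]] <- data.frame(
        direction = "outbound", start = seg[1], end = seg[length(seg)],
        straightness = straightness_index(series$x[seg], series$y[seg]))
  }
  arr <- which(!is.na(d) & d > roost_radius_m)
  arr <- if (length(arr)) arr[length(arr)] else NA
  if (!is.na(arr)) {
    fb <- .state_runs(st, 1L)
    fb <- fb[fb$end < arr & fb$length > 1, , drop = FALSE]
    from <- if (nrow(fb)) fb$end[nrow(fb)] else 1L
    seg <- if (full_path) from:arr else {
      cr <- .state_runs(st[seq_len(n)], commuting)
      cr <- cr[cr$start >= from & cr$start <= arr, , drop = FALSE]
      if (nrow(cr)) cr$start[1]:min(cr$end[nrow(cr)], arr) else integer(0)
    }
    if (length(seg) >= 2)
      out[[length(out) + 1L]] <- data.frame(
        direction = "inbound", start = seg[1], end = seg[length(seg)],
        straightness = straightness_index(series$x[seg], series$y[seg]))
  }
  if (!length(out))
    return(data.frame(direction = character(0), start = integer(0),
                      end = integer(0), straightness = numeric(0)))
  do.call(rbind, out)
}

#' Extract foraging locations from a decoded night
#'
#' A foraging bout is a maximal run of foraging-state slots; bouts of length
#' one are discarded, and the first location of each retained bout becomes a
#' foraging location with distance and bearing to the roost and an
#' on-home-island flag.
#'
#' @param series a `bat_steps` series.
#' @param states decode result aligned with `series`.
#' @param roost `c(x, y)` roost (m).
#' @param ls a [landscape()]; `NULL` leaves `on_home_island` as `NA`.
#' @param meta named list merged into the output (individual/colony/season/
#'   provenance columns).
#' @return data frame of foraging locations (possibly 0 rows).
#' @export
extract_foraging_locations <- function(series, states, roost, ls = NULL,
                                       meta = list()) {
  runs <- .state_runs(states$state, 1L)
  runs <- runs[runs$length > 1, , drop = FALSE]
  if (nrow(runs)) {
    # a bout anchors at its first slot with a known location
    first_xy <- t(vapply(runs$start, function(s0) {
      e <- runs$end[runs$start == s0][1]
      i <- s0 - 1L + which(!is.na(series$x[s0:e]))[1]
      if (is.na(i)) c(NA_real_, NA_real_) else c(series$x[i], series$y[i])
    }, numeric(2)))
    # drop unlocated bouts and bouts anchored exactly at the roost
    # (distance 0 has no defined bearing)
    ok <- !is.na(first_xy[, 1]) &
      (first_xy[, 1] != roost[1] | first_xy[, 2] != roost[2])
    runs <- runs[ok, , drop = FALSE]; first_xy <- first_xy[ok, , drop = FALSE]
  }
  if (!nrow(runs)) {
    out <- data.frame(x = numeric(0), y = numeric(0), slot = integer(0),
                      distance_km = numeric(0), angle_rad = numeric(0),
                      compass_deg = numeric(0), on_home_island = logical(0))
  } else {
    ad <- angle_distance_to_roost(first_xy[, 1], first_xy[, 2], roost)
    out <- data.frame(x = first_xy[, 1], y = first_xy[, 2], slot = runs$start,
                      distance_km = ad$distance_km, angle_rad = ad$angle_rad,
                      compass_deg = ad$compass_deg,
                      on_home_island = if (is.null(ls)) NA else
                        is_on_home_island(first_xy[, 1], first_xy[, 2], ls))
  }
  for (nm in names(meta)) out[[nm]] <- if (nrow(out)) meta[[nm]] else
    meta[[nm]][0]
  out
}

#' Per-night on/off-island foraging-time proportions
#'
#' Classifies every foraging-state slot with a known location by home-island
#' membership. Nights with zero located foraging slots are excluded (and
#' listed in attribute `"excluded"`).
#'
#' @param series_list list of `bat_steps`.
#' @param states_list matching list of decode results.
#' @param ls a [landscape()].
#' @param meta_list optional list of per-night named lists (id columns).
#' @return data frame with per-night `n_on`, `n_off`, `prop_on`, `prop_off`
#'   (summing to 1).
#' @export
foraging_time_proportions <- function(series_list, states_list, ls,
                                      meta_list = NULL) {
  rows <- list(); excluded <- integer(0)
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]; st <- states_list[[i]]$state
    f <- which(st == 1L & !is.na(s$x))
    if (!length(f)) { excluded <- c(excluded, i); next }
    on <- sum(is_on_home_island(s$x[f], s$y[f], ls))
    row <- data.frame(night = i, n_on = on, n_off = length(f) - on,
                      prop_on = on / length(f),
                      prop_off = 1 - on / length(f))
    if (!is.null(meta_list)) for (nm in names(meta_list[[i]]))
      row[[nm]] <- meta_list[[i]][[nm]]
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(night = integer(0), n_on = integer(0), n_off = integer(0),
               prop_on = numeric(0), prop_off = numeric(0))
  attr(out, "excluded") <- excluded
  out
}

#' Binomial GLM on per-night foraging counts
#'
#' Logit-link GLM (iteratively reweighted least squares via [stats::glm()])
#' on aggregated per-night (on, off) slot counts -- the likelihood is
#' identical to per-slot Bernoulli rows but the design matrix is one row per
#' night. Wald z tests; complete separation is reported as a warning.
#'
#' @param data data frame containing `n_on`, `n_off` and the design factors.
#' @param formula RHS-only or two-sided formula for the fixed effects, e.g.
#'   `~ period + location` (the response is built from the counts).
#' @return the fitted `glm` object; `summary()` gives coefficients, standard
#'   errors and p-values.
#' @export
fit_binomial_glm <- function(data, formula = ~ 1) {
  rhs <- if (length(formula) == 3) formula[c(1, 3)] else formula
  f <- stats::as.formula(paste("cbind(n_on, n_off)", paste(deparse(rhs), collapse = "")))
  fit <- stats::glm(f, family = stats::binomial(), data = data)
  mu <- stats::fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8))
    warning("fitted probabilities of 0 or 1: possible complete separation; ",
            "Wald tests unreliable")
  fit
}

#' Nectar-tree requirement for a colony
#'
#' Number of simultaneously flowering balsa trees needed to feed a colony
#' for one night, given that one tree feeds between `bats_per_tree_min` and
#' `bats_per_tree_max` bats: the minimum assumes maximally shareable trees
#' (`ceil(colony / max)`), the maximum minimally shareable ones
#' (`floor(colony / min)`).
#'
#' @param colony_size number of bats.
#' @param bats_per_tree_min,bats_per_tree_max bats fed per tree per night.
#' @return named numeric `c(min_trees, max_trees)`.
#' @export
balsa_tree_requirement <- function(colony_size, bats_per_tree_min = 3,
                                   bats_per_tree_max = 7) {
  stopifnot(colony_size > 0, bats_per_tree_min > 0, bats_per_tree_max > 0)
  if (bats_per_tree_min > bats_per_tree_max)
    stop("bats_per_tree_min exceeds bats_per_tree_max", call. = FALSE)
  c(min_trees = ceiling(colony_size / bats_per_tree_max),
    max_trees = floor(colony_size / bats_per_tree_min))
}
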