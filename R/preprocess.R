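# Track cleaning: speed/range outlier removal, downsampling to a fixed
# interval, regularization to a complete time grid with missing markers,
# and complete-night classification.

#' Remove implausible GPS fixes
#'
#' Sequential speed filter plus an over-water range rule. A fix is removed
#' when (i) the speed implied from the previous *retained* fix exceeds
#' `max_speed` (15 m/s is beyond this species' flight capability), or
#' (ii) it lies over water farther than `max_range_km` from the roost
#' (beyond any plausible commute). The sequential formulation means a single
#' bad fix does not condemn its neighbours, and the filter is idempotent.
#'
#' @param track a `bat_track` with projected coordinates.
#' @param ls a [landscape()] (used for the over-water rule); `NULL` skips it.
#' @param max_speed m/s.
#' @param max_range_km over-water distance limit from the roost (km).
#' @return the cleaned track; attribute `"removal_log"` is a data frame with
#'   one row per removed fix (`time`, `reason`).
#' @export
remove_outliers <- function(track, ls = NULL, max_speed = 15,
                            max_range_km = 60) {
  fx <- track$fixes
  n <- nrow(fx)
  roost <- if (!is.null(ls)) ls$roosts[[track$colony_id]] else NULL
  reason <- character(0); when <- fx$time[0]
  if (!is.null(ls) && !is.null(roost)) {
    over <- !is_on_land(fx$x, fx$y, ls) &
      sqrt((fx$x - roost[1])^2 + (fx$y - roost[2])^2) > max_range_km * 1000
    if (any(over)) {
      reason <- c(reason, rep("water_range", sum(over)))
      when <- c(when, fx$time[over])
      fx <- fx[!over, , drop = FALSE]
      n <- nrow(fx)
    }
  }
  if (n > 1) {
    keep <- logical(n); keep[1] <- TRUE
    last <- 1L
    for (i in 2:n) {
      dt <- as.numeric(fx$time[i]) - as.numeric(fx$time[last])
      sp <- sqrt((fx$x[i] - fx$x[last])^2 + (fx$y[i] - fx$y[last])^2) / dt
      if (sp <= max_speed) { keep[i] <- TRUE; last <- i }
    }
    if (any(!keep)) {
      reason <- c(reason, rep("speed", sum(!keep)))
      when <- c(when, fx$time[!keep])
      fx <- fx[keep, , drop = FALSE]
    }
  }
  if (nrow(fx) == 0)
    stop("empty-track error: all fixes removed by the outlier filter",
         call. = FALSE)
  rownames(fx) <- NULL
  fx$speed <- .track_speeds(fx)
  track$fixes <- fx
  log <- data.frame(time = when, reason = reason)
  attr(track, "removal_log") <- log[order(log$time), , drop = FALSE]
  track
}

#' Downsample a track to a target interval
#'
#' Retains, for each time on the grid anchored at the first fix, the nearest
#' fix within `target_interval / 2`; a fix is never used for two grid times.
#'
#' @param track a `bat_track`.
#' @param target_interval target sampling interval (s).
#' @return the downsampled track with `interval` set.
#' @export
downsample <- function(track, target_interval = 120) {
  fx <- track$fixes
  t0 <- as.numeric(fx$time)
  if (nrow(fx) >= 2) {
    native <- stats::median(diff(t0))
    if (native > target_interval) {
      warning("native interval (", round(native), " s) exceeds target; track passed through")
      track$interval <- native
      return(track)
    }
  }
  grid <- seq(t0[1], t0[length(t0)], by = target_interval)
  used <- rep(FALSE, nrow(fx))
  pick <- integer(0)
  for (g in grid) {
    cand <- which(!used & abs(t0 - g) <= target_interval / 2)
    if (!length(cand)) next
    i <- cand[which.min(abs(t0[cand] - g))]
    used[i] <- TRUE
    pick <- c(pick, i)
  }
  fx <- fx[pick, , drop = FALSE]
  rownames(fx) <- NULL
  fx$speed <- .track_speeds(fx)
  track$fixes <- fx
  track$interval <- target_interval
  track
}

#' Regularize a track onto a complete time grid
#'
#' Builds the full arithmetic grid from the first to the last fix at
#' `interval` seconds, inserting missing slots where no fix falls within
#' half an interval of a grid time; computes step lengths (metres, from each
#' slot to the next) and turning angles (radians, counterclockwise positive
#' in (-pi, pi], defined where three consecutive locations exist).
#'
#' @param track a downsampled `bat_track`.
#' @param interval grid interval (s); defaults to the track's.
#' @return an object of class `"bat_steps"`: data frame with columns `time`,
#'   `x`, `y`, `obs` (observed?), `step`, `angle`, plus attributes `interval`
#'   and `track_meta`.
#' @export
regularize <- function(track, interval = track$interval) {
  fx <- track$fixes
  if (is.na(interval)) stop("track has no interval; downsample first", call. = FALSE)
  if (nrow(fx) < 3)
    stop("insufficient-data error: fewer than 3 fixes", call. = FALSE)
  t0 <- as.numeric(fx$time)
  grid <- seq(t0[1], t0[length(t0)], by = interval)
  idx <- rep(NA_integer_, length(grid))
  slot <- round((t0 - t0[1]) / interval) + 1L
  ok <- abs(t0 - (t0[1] + (slot - 1) * interval)) <= interval / 2 &
    slot >= 1 & slot <= length(grid)
  idx[slot[ok]] <- which(ok)
  x <- ifelse(is.na(idx), NA_real_, fx$x[idx])
  y <- ifelse(is.na(idx), NA_real_, fx$y[idx])
  if (sum(!is.na(x)) < 3)
    stop("insufficient-data error: fewer than 3 non-missing locations",
         call. = FALSE)
  n <- length(grid)
  step <- c(sqrt(diff(x)^2 + diff(y)^2), NA_real_)
  dx <- diff(x); dy <- diff(y)
  hd <- atan2(dy, dx)                     # heading of step t -> t+1
  ang <- rep(NA_real_, n)
  if (n >= 3)
    ang[2:(n - 1)] <- wrap_angle(hd[2:(n - 1)] - hd[1:(n - 2)])
  df <- data.frame(time = as.POSIXct(grid, origin = "1970-01-01",
                                     tz = attr(fx$time, "tzone") %||% "UTC"),
                   x = x, y = y, obs = !is.na(x), step = step, angle = ang)
  structure(df, interval = interval,
            track_meta = track[c("individual_id", "colony_id", "season",
                                 "period", "night_date")],
            class = c("bat_steps", "data.frame"))
}

#' Classify a bat-night as complete or incomplete
#'
#' Complete means both commutes were recorded: the first and last fixes lie
#' within `roost_radius_m` of the roost and the night's maximum displacement
#' exceeds that radius (so the bat actually left).
#'
#' @param track a cleaned `bat_track`.
#' @param roost `c(x, y)` roost coordinates (m).
#' @param roost_radius_m radius defining "at the roost".
#' @return `"complete"` or `"incomplete"`.
#' @export
classify_night <- function(track, roost, roost_radius_m = 500) {
  fx <- track$fixes
  d <- sqrt((fx$x - roost[1])^2 + (fx$y - roost[2])^2)
  n <- length(d)
  if (d[1] <= roost_radius_m && d[n] <= roost_radius_m &&
      max(d) > roost_radius_m) "complete" else "incomplete"
}
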