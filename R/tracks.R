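# GPS track ingestion. A bat-night track is one individual's fixes inside a
# single 18:00-06:00 local window, with projected coordinates and derived
# ground speeds.

#' Track-reading configuration
#'
#' @param crs a [tm_crs()] projection.
#' @param tz Olson timezone of the study site (used for the night window).
#' @param window numeric `c(start, end)` hours of the nightly recording
#'   window; default `c(18, 6)` (half-open: a fix at exactly `start` belongs
#'   to the night, a fix at exactly `end` does not).
#' @param columns column mapping for other CSV dialects; names `timestamp`,
#'   `lon`, `lat`, `id` are required.
#' @export
track_config <- function(crs = tm_crs(), tz = "America/Panama",
                         window = c(18, 6),
                         columns = list(timestamp = "timestamp",
                                        lon = "location-long",
                                        lat = "location-lat",
                                        id = "individual-local-identifier")) {
  structure(list(crs = crs, tz = tz, window = window, columns = columns),
            class = "bat_track_config")
}

new_track <- function(individual_id, colony_id, season, period, night_date,
                      fixes, interval = NA_real_) {
  structure(list(individual_id = individual_id, colony_id = colony_id,
                 season = season, period = period, night_date = night_date,
                 interval = interval, fixes = fixes),
            class = "bat_track")
}

#' @export
print.bat_track <- function(x, ...) {
  cat(sprintf("<bat_track> %s (%s, %s) night %s: %d fixes",
              x$individual_id, x$colony_id, x$season,
              format(x$night_date), nrow(x$fixes)))
  if (!is.na(x$interval)) cat(sprintf(" @ %gs", x$interval))
  cat("\n")
  invisible(x)
}

#' @export
plot.bat_track <- function(x, ..., asp = 1) {
  graphics::plot(x$fixes$x, x$fixes$y, type = "l", asp = asp,
                 xlab = "x (m)", ylab = "y (m)",
                 main = paste(x$individual_id, format(x$night_date)), ...)
  graphics::points(x$fixes$x[1], x$fixes$y[1], pch = 19)
  invisible(x)
}

# ground speed between consecutive fixes (m/s), attributed to the later fix
.track_speeds <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(rep(NA_real_, n))
  dt <- as.numeric(diff(fixes$time), units = "secs")
  dd <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)
  c(NA_real_, dd / dt)
}

#' Read Movebank-dialect GPS tracks as bat-nights
#'
#' Splits each individual's fixes at the nightly window boundary into
#' bat-night tracks, sorts fixes by time, projects coordinates, and attaches
#' colony/season metadata. Fixes outside the recording window are dropped
#' with a warning (count reported).
#'
#' @param path CSV file with at least timestamp, location-long, location-lat
#'   and individual identifier columns (or the mapping in
#'   `config$columns`). Timestamps are parsed as UTC (`"yyyy-mm-dd HH:MM:SS"`).
#' @param metadata data frame with columns `individual_id`, `colony_id`,
#'   `season`, `period`.
#' @param config a [track_config()].
#' @return list of `bat_track` objects, ordered by individual then night.
#' @export
read_tracks <- function(path, metadata, config = track_config()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- config$columns
  miss <- setdiff(unlist(cols), names(raw))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(
    time = as.POSIXct(raw[[cols$timestamp]], tz = "UTC"),
    lon = as.numeric(raw[[cols$lon]]),
    lat = as.numeric(raw[[cols$lat]]),
    id = as.character(raw[[cols$id]]),
    stringsAsFactors = FALSE)
  if (anyNA(df$time)) stop("format error: unparseable timestamps", call. = FALSE)
  unknown <- setdiff(unique(df$id), metadata$individual_id)
  if (length(unknown))
    stop("metadata error: individual(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  df <- df[order(df$id, df$time), ]
  # assign each fix to a bat-night by local clock time
  lt <- as.POSIXlt(df$time, tz = config$tz)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  local_date <- as.Date(format(df$time, tz = config$tz))
  w <- config$window
  in_evening <- hour >= w[1]
  in_morning <- hour < w[2]
  keep <- in_evening | in_morning
  if (any(!keep))
    warning(sum(!keep), " fix(es) outside the ", w[1], ":00-", w[2],
            ":00 window dropped")
  df <- df[keep, ]
  night <- local_date[keep]
  night[in_morning[keep]] <- night[in_morning[keep]] - 1L
  xy <- project_lonlat(df$lon, df$lat, config$crs)
  df$x <- xy[, 1]; df$y <- xy[, 2]
  out <- list()
  for (id in unique(df$id)) {
    meta <- metadata[metadata$individual_id == id, , drop = FALSE][1, ]
    sub <- df$id == id
    for (nd in sort(unique(night[sub]))) {
      fx <- df[sub & night == nd, c("time", "lon", "lat", "x", "y")]
      fx <- fx[!duplicated(fx$time), ]
      rownames(fx) <- NULL
      fx$speed <- .track_speeds(fx)
      out[[length(out) + 1L]] <- new_track(
        individual_id = id, colony_id = meta$colony_id,
        season = meta$season, period = meta$period,
        night_date = as.Date(nd, origin = "1970-01-01"), fixes = fx)
    }
  }
  out
}

#' Write tracks to CSV
#'
#' Movebank-style columns plus projected coordinates and the bat-night date.
#'
#' @param tracks list of `bat_track`.
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(
      `timestamp` = format(tr$fixes$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      `location-long` = tr$fixes$lon, `location-lat` = tr$fixes$lat,
      `individual-local-identifier` = tr$individual_id,
      colony_id = tr$colony_id, season = tr$season, period = tr$period,
      night_date = format(tr$night_date),
      x = tr$fixes$x, y = tr$fixes$y, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
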