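# Ellipsoidal transverse-Mercator projection (WGS84), used to put GPS fixes
# on a local metric grid. Step lengths, the 15 m/s speed filter and all
# distance/angle summaries are computed on this grid.

#' Define a transverse-Mercator (UTM-style) projection
#'
#' Defaults to UTM zone 17N (central meridian 81 W), the metric CRS
#' appropriate for the Bocas del Toro archipelago; pass `zone` or
#' `lon0` to relocate.
#'
#' @param zone UTM zone number (sets the central meridian `lon0 = 6*zone - 183`).
#' @param lon0 central meridian in degrees; overrides `zone` when given.
#' @param k0 scale factor on the central meridian.
#' @param false_easting,false_northing offsets in metres.
#' @return an object of class `"tm_crs"`.
#' @export
tm_crs <- function(zone = 17, lon0 = NULL, k0 = 0.9996,
                   false_easting = 500000, false_northing = 0) {
  if (is.null(lon0)) lon0 <- 6 * zone - 183
  structure(list(a = 6378137, f = 1 / 298.257223563, lon0 = lon0, k0 = k0,
                 fe = false_easting, fn = false_northing),
            class = "tm_crs")
}

# meridional arc length M(phi) (Snyder 3-21)
.tm_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
       (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
       (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
       (35 * e2^3 / 3072) * sin(6 * phi))
}

#' Project geographic to planar coordinates
#'
#' Forward ellipsoidal transverse-Mercator. Accurate to well under a metre
#' within a few degrees of the central meridian; warns outside +/- 6 degrees.
#'
#' @param lon,lat WGS84 coordinates in degrees.
#' @param crs a [tm_crs()] object.
#' @return a two-column matrix with columns `x`, `y` in metres.
#' @export
project_lonlat <- function(lon, lat, crs = tm_crs()) {
  dl <- lon - crs$lon0
  dl <- ((dl + 180) %% 360) - 180
  if (any(abs(dl) > 6, na.rm = TRUE))
    warning("coordinates more than 6 degrees from the central meridian; projection error grows")
  e2 <- crs$f * (2 - crs$f)
  ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  lam <- dl * pi / 180
  N <- crs$a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- lam * cos(phi)
  M <- .tm_arc(phi, crs$a, e2)
  x <- crs$fe + crs$k0 * N *
    (A + (1 - Tt + C) * A^3 / 6 +
       (5 - 18 * Tt + Tt^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- crs$fn + crs$k0 *
    (M + N * tan(phi) *
       (A^2 / 2 + (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
          (61 - 58 * Tt + Tt^2 + 600 * C - 330 * ep2) * A^6 / 720))
  cbind(x = x, y = y)
}

#' Inverse projection: planar to geographic coordinates
#'
#' @param x,y planar coordinates in metres.
#' @param crs a [tm_crs()] object.
#' @return a two-column matrix with columns `lon`, `lat` in degrees.
#' @export
unproject_xy <- function(x, y, crs = tm_crs()) {
  e2 <- crs$f * (2 - crs$f)
  ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M <- (y - crs$fn) / crs$k0
  mu <- M / (crs$a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu +
    (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- crs$a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- crs$a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- (x - crs$fe) / (N1 * crs$k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
            (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  cbind(lon = crs$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
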