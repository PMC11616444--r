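# Landscape model: land polygons, home island, roost coordinates.
# Polygons are stored as rings (two-column x/y matrices in projected metres);
# the first ring listed as `home_island` is the roost island.

#' Construct a landscape
#'
#' @param land list of rings (two-column matrices, projected metres); holes are
#'   not supported.
#' @param home_island integer index into `land` giving the roost island ring.
#' @param roosts named list mapping `colony_id` to `c(x, y)` roost coordinates.
#' @param crs the [tm_crs()] used for geographic conversion.
#' @return an object of class `"bat_landscape"`.
#' @export
landscape <- function(land, home_island = 1L, roosts = list(), crs = tm_crs()) {
  land <- lapply(land, function(r) {
    r <- as.matrix(r)
    colnames(r) <- c("x", "y")
    r
  })
  ls <- structure(list(land = land, home_island = as.integer(home_island),
                       roosts = roosts, crs = crs),
                  class = "bat_landscape")
  ls$bbox <- landscape_bbox(ls)
  for (cid in names(roosts)) {
    r <- roosts[[cid]]
    if (!is_on_home_island(r[1], r[2], ls))
      stop("roost '", cid, "' does not lie on the home island", call. = FALSE)
  }
  ls
}

#' @rdname landscape
#' @param x a `bat_landscape`.
#' @param ... unused.
#' @export
print.bat_landscape <- function(x, ...) {
  cat("<bat_landscape>", length(x$land), "land polygon(s),",
      length(x$roosts), "roost(s)\n")
  bb <- x$bbox
  cat(sprintf("  bbox: x [%.0f, %.0f] m, y [%.0f, %.0f] m\n",
              bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

landscape_bbox <- function(ls) {
  xs <- unlist(lapply(ls$land, function(r) r[, 1]))
  ys <- unlist(lapply(ls$land, function(r) r[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# distance from points to the edges of a ring; used so that polygon
# boundaries count as land (the raw even-odd test is open on edges)
.dist_to_ring <- function(x, y, ring) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-12
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    t <- pmin(1, pmax(0, ((x[i] - x1) * dx + (y[i] - y1) * dy) / len2))
    out[i] <- sqrt(min((x[i] - (x1 + t * dx))^2 + (y[i] - (y1 + t * dy))^2))
  }
  out
}

.in_rings <- function(x, y, rings, eps = 1e-6) {
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (r in rings) {
    inside <- inside | mgcv::in.out(rbind(r, r[1, , drop = FALSE]), pts)
    todo <- which(!inside)
    if (length(todo)) # boundary counts as land
      inside[todo] <- .dist_to_ring(x[todo], y[todo], r) <= eps
  }
  inside
}

#' Point-in-landscape tests
#'
#' `is_on_land()` tests membership in any land polygon; `is_on_home_island()`
#' tests the roost island only. Polygon boundaries count as land.
#'
#' @param x,y projected coordinates (metres), vectorized.
#' @param ls a [landscape()].
#' @return logical vector.
#' @export
is_on_land <- function(x, y, ls) {
  .in_rings(x, y, ls$land)
}

#' @rdname is_on_land
#' @export
is_on_home_island <- function(x, y, ls) {
  .in_rings(x, y, ls$land[ls$home_island])
}

#' Read a landscape from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon/MultiPolygon
#' features in WGS84; outer rings only. The home island is the feature whose
#' property `home_island` is true, else the first ring.
#'
#' @param path GeoJSON file.
#' @param roosts named list mapping colony id to `c(lon, lat)`.
#' @param crs a [tm_crs()].
#' @export
read_landscape_geojson <- function(path, roosts = list(), crs = tm_crs()) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(list(geometry = gj, properties = list()))
  rings <- list(); home <- NA_integer_
  for (f in feats) {
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (p in polys) {
      outer <- do.call(rbind, lapply(p[[1]], function(c2) c(c2[[1]], c2[[2]])))
      xy <- project_lonlat(outer[, 1], outer[, 2], crs)
      # drop the closing vertex; rings are implicitly closed
      if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
      rings[[length(rings) + 1L]] <- xy
      if (is.na(home) && isTRUE(f$properties$home_island))
        home <- length(rings)
    }
  }
  if (!length(rings)) stop("no polygons found in ", path, call. = FALSE)
  if (is.na(home)) home <- 1L
  roosts_xy <- lapply(roosts, function(ll) {
    p <- project_lonlat(ll[1], ll[2], crs)
    c(x = p[1, 1], y = p[1, 2])
  })
  landscape(rings, home_island = home, roosts = roosts_xy, crs = crs)
}

#' Write a landscape to GeoJSON
#'
#' @param ls a [landscape()].
#' @param path output file.
#' @export
write_landscape_geojson <- function(ls, path) {
  feats <- lapply(seq_along(ls$land), function(i) {
    r <- ls$land[[i]]
    ll <- unproject_xy(r[, 1], r[, 2], ls$crs)
    ll <- rbind(ll, ll[1, ])  # close the ring
    coords <- lapply(seq_len(nrow(ll)), function(j) c(ll[j, 1], ll[j, 2]))
    list(type = "Feature",
         properties = list(home_island = (i == ls$home_island)),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# regular polygon ring (approximate circle), optionally jittered in radius
.circle_ring <- function(cx, cy, radius, n = 48, jitter = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius * (1 + jitter * sin(3 * th + stats::runif(1, 0, 2 * pi)) *
                   stats::runif(n, 0.3, 1))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a synthetic island-plus-mainland landscape
#'
#' Builds a roost island and, across a configurable water gap, a mainland
#' block wide enough to host off-island foraging areas 15-25 km from the
#' roost. Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param geometry_spec list with elements `island_radius` (m),
#'   `island_center` (c(x, y), m), `water_gap` (m, island edge to mainland
#'   edge), `mainland_extent` (c(width, height), m; `c(0, 0)` omits the
#'   mainland), `jitter` (fractional coastline jitter), `roosts` (named list
#'   of roost offsets from the island centre).
#' @param crs a [tm_crs()]; the default places the island near 9.4 N, 82.25 W.
#' @return a [landscape()].
#' @export
make_landscape <- function(seed = 1,
                           geometry_spec = list(),
                           crs = tm_crs()) {
  spec <- utils::modifyList(list(
    island_radius = 4000,
    island_center = c(363000, 1039000),  # UTM 17N, Bocas del Toro region
    water_gap = 10000,
    mainland_extent = c(45000, 35000),   # reach east/south of the notch corner
    jitter = 0.06,
    roosts = list(colony1 = c(0, 1500), colony2 = c(-1500, -1000),
                  colony3 = c(1500, -500))
  ), geometry_spec)
  if (spec$water_gap <= 0 && any(spec$mainland_extent > 0))
    stop("degenerate geometry_spec: island and mainland overlap", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  cx <- spec$island_center[1]; cy <- spec$island_center[2]
  rings <- list(.circle_ring(cx, cy, spec$island_radius, n = 72,
                             jitter = spec$jitter))
  if (all(spec$mainland_extent > 0)) {
    # L-shaped mainland wrapping the island to the south and west (the
    # archipelago sits in the crook of the coastline), separated from the
    # island edge by the water gap; inner coasts lightly jittered
    g <- spec$island_radius * (1 + spec$jitter) + spec$water_gap + 300
    ew <- spec$mainland_extent[1]   # how far land runs east of the notch
    nh <- spec$mainland_extent[2]   # how far land runs north of the notch
    xw <- cx - g; ys <- cy - g      # inner notch corner
    x0 <- cx - 60000; y0 <- cy - 45000  # outer extent (SW)
    jit <- function(u) spec$jitter * 13000 * abs(sin(u / 9000)) *
      stats::runif(length(u), 0.4, 1)
    xs_s <- seq(xw, cx + ew, length.out = 30)       # south coast, W to E
    ys_w <- seq(cy + nh, ys, length.out = 25)       # west coast, N to S
    ring <- rbind(
      cbind(x = xw - jit(ys_w), y = ys_w),          # west coast going south
      cbind(x = xs_s, y = ys - jit(xs_s)),          # south coast going east
      cbind(x = c(cx + ew, cx + ew, x0, x0),
            y = c(ys - 2000, y0, y0, cy + nh)))     # outer boundary
    rings[[2]] <- ring
  }
  roosts <- lapply(spec$roosts, function(off) c(x = cx + off[1], y = cy + off[2]))
  landscape(rings, home_island = 1L, roosts = roosts, crs = crs)
}

# save/restore .Random.seed so generators are self-contained
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
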