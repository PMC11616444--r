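# Spatial representation of the fitted distance/bearing model: per-cell
# product of the marginal predictive densities of distance and bearing,
# 95% highest-density contours, and pairwise colony overlap percentages
# clipped to land.

#' Rasterized foraging-density map from a hierarchical fit
#'
#' For each cell centre, computes the distance `r` and bearing `phi` to the
#' roost (south-zero clockwise convention) and evaluates the scaled product
#' `p(r) * p(phi)` of the posterior marginal predictive densities:
#' `p(r)` averages `Normal(r; mu_d, sqrt(sigma_d^2 + tau_d^2))` over
#' posterior draws, `p(phi)` averages the von Mises density with a
#' random-effect offset drawn per posterior draw. By default the plain
#' product is used (no polar Jacobian); `jacobian = TRUE` divides by `r`.
#'
#' @param fit a converged [fit_hier()] result.
#' @param roost `c(x, y)` roost (m).
#' @param ls a [landscape()] providing the bounding box.
#' @param cell_size cell edge (m).
#' @param exclude_home_island zero the density on the home island (maps of
#'   "foraging beyond the home island")?
#' @param n_draw_max posterior draws used per cell (thinned evenly).
#' @param jacobian divide by `r` (polar area correction)?
#' @param pad bounding-box padding (m).
#' @param seed seed for the per-draw random-effect offsets.
#' @return an object of class `"bat_raster"`: `values` matrix (nx x ny),
#'   `x`, `y` cell-centre coordinates, `cell_size`, and the call metadata.
#' @export
pdf_map <- function(fit, roost, ls, cell_size = 500,
                    exclude_home_island = FALSE, n_draw_max = 200,
                    jacobian = FALSE, pad = 5000, seed = 1) {
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  bb <- ls$bbox + c(-pad, pad, -pad, pad)
  xs <- seq(bb[1] + cell_size / 2, bb[2], by = cell_size)
  ys <- seq(bb[3] + cell_size / 2, bb[4], by = cell_size)
  dr <- fit$draws
  idx <- unique(round(seq(1, nrow(dr), length.out = min(n_draw_max, nrow(dr)))))
  mu_d <- dr[idx, "mu_d"]; sd_d <- dr[idx, "eff_sd_d"]
  mu_t <- dr[idx, "mu_theta"]; kap <- dr[idx, "kappa"]
  a_off <- stats::rnorm(length(idx), 0, dr[idx, "tau_theta"])
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  dx <- gx - roost[1]; dy <- gy - roost[2]
  r_km <- sqrt(dx^2 + dy^2) / 1000
  phi <- wrap_angle(atan2(-dx, -dy))
  pr <- numeric(length(gx)); pphi <- numeric(length(gx))
  for (k in seq_along(idx)) {  # average predictive densities over draws
    pr <- pr + stats::dnorm(r_km, mu_d[k], sd_d[k])
    pphi <- pphi + dvonmises(phi, mu_t[k] + a_off[k], kap[k])
  }
  val <- (pr / length(idx)) * (pphi / length(idx))
  if (jacobian) val <- val / pmax(r_km, cell_size / 2000)
  if (exclude_home_island)
    val[is_on_home_island(gx, gy, ls)] <- 0
  structure(list(values = matrix(val, nrow = length(xs)), x = xs, y = ys,
                 cell_size = cell_size, roost = roost),
            class = "bat_raster")
}

#' @export
print.bat_raster <- function(x, ...) {
  cat(sprintf("<bat_raster> %d x %d cells of %g m; total mass %.4g\n",
              length(x$x), length(x$y), x$cell_size,
              sum(x$values) * x$cell_size^2))
  invisible(x)
}

#' @export
plot.bat_raster <- function(x, ..., mask = NULL) {
  v <- x$values
  if (!is.null(mask)) v[!mask] <- NA
  graphics::image(x$x, x$y, v, asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Highest-density contour mask
#'
#' Selects the smallest set of cells containing at least `level` of the
#' raster's total mass: cells are ranked by density (ties broken by cell
#' index for determinism) and accumulated until the level is reached.
#'
#' @param raster a [pdf_map()] result.
#' @param level mass fraction (default 0.95).
#' @return logical matrix of the raster's dimensions.
#' @export
contour_mask <- function(raster, level = 0.95) {
  v <- as.vector(raster$values)
  tot <- sum(v)
  if (tot <= 0) stop("raster has no mass", call. = FALSE)
  ord <- order(v, seq_along(v), decreasing = TRUE)
  cum <- cumsum(v[ord]) / tot
  k <- which(cum >= level)[1]
  mask <- logical(length(v))
  mask[ord[seq_len(k)]] <- TRUE
  matrix(mask, nrow = nrow(raster$values))
}

# land mask on a raster grid (cell centres)
.land_mask <- function(raster, ls) {
  gx <- rep(raster$x, times = length(raster$y))
  gy <- rep(raster$y, each = length(raster$x))
  matrix(is_on_land(gx, gy, ls), nrow = length(raster$x))
}

#' Pairwise overlap percentage of two contour masks
#'
#' Both masks are clipped to land, then the directed overlaps are returned:
#' `a_in_b` = 100 * area(A intersect B) / area(A), and conversely. Cells are
#' equal-area, so areas are cell counts.
#'
#' @param mask_a,mask_b logical matrices on the same grid
#'   (from [contour_mask()]).
#' @param raster the raster the masks belong to (supplies the grid).
#' @param ls a [landscape()] for clipping; `NULL` skips clipping.
#' @return named numeric `c(a_in_b, b_in_a)` in percent.
#' @export
overlap_percentage <- function(mask_a, mask_b, raster, ls = NULL) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are not on the same grid", call. = FALSE)
  if (!is.null(ls)) {
    land <- .land_mask(raster, ls)
    mask_a <- mask_a & land
    mask_b <- mask_b & land
  }
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na == 0 || nb == 0)
    stop("undefined overlap: a mask has zero area after land clipping",
         call. = FALSE)
  ni <- sum(mask_a & mask_b)
  c(a_in_b = 100 * ni / na, b_in_a = 100 * ni / nb)
}
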