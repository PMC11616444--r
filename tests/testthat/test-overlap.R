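mk_conc_fit <- function(mu_d, mu_theta, sd = 2.5, kappa = 8) {
  n <- 200
  structure(list(draws = cbind(
    mu_d = rep(mu_d, n), sigma_d = sd, tau_d = 0, eff_sd_d = sd,
    mu_theta = mu_theta, kappa = kappa, tau_theta = 0,
    eff_sd_theta = NA_real_, chain = 1)), class = "bat_hier")
}

test_that("the density peak sits at the fitted distance and bearing", {
  f <- mk_conc_fit(20, 0.3, sd = 0.25, kappa = 400)
  roost <- bf_ls$roosts$colony1
  r <- pdf_map(f, roost, bf_ls, cell_size = 500)
  am <- which(r$values == max(r$values), arr.ind = TRUE)
  got <- c(r$x[am[1]], r$y[am[2]])
  expected <- roost + 20000 * c(-sin(0.3), -cos(0.3))
  expect_lt(sqrt(sum((got - expected)^2)), 2 * 500)
  expect_true(all(r$values >= 0))
  expect_error(pdf_map(f, roost, bf_ls, cell_size = -1), "cell_size")
})

test_that("total mass is stable under grid refinement", {
  f <- mk_conc_fit(20, 0.3)
  roost <- bf_ls$roosts$colony1
  m1 <- with(pdf_map(f, roost, bf_ls, 500), sum(values) * 500^2)
  m2 <- with(pdf_map(f, roost, bf_ls, 1000), sum(values) * 1000^2)
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("a diffuse-bearing map is rotationally symmetric before clipping", {
  f <- mk_conc_fit(15, 0, sd = 2.5, kappa = 0)
  roost <- bf_ls$roosts$colony1
  r <- pdf_map(f, roost, bf_ls, 500)
  th <- seq(-pi, pi, length.out = 17)[-17]
  px <- roost[1] - 15000 * sin(th); py <- roost[2] - 15000 * cos(th)
  bb <- bf_ls$bbox
  ok <- px > bb[1] & px < bb[2] & py > bb[3] & py < bb[4]
  vals <- vapply(which(ok), function(i) {
    ix <- which.min(abs(r$x - px[i])); iy <- which.min(abs(r$y - py[i]))
    rc <- sqrt((r$x[ix] - roost[1])^2 + (r$y[iy] - roost[2])^2) / 1000
    r$values[ix, iy] / stats::dnorm(rc, 15, 2.5)  # remove radial profile
  }, 0)
  expect_lt(stats::sd(vals) / mean(vals), 1e-8)
})

test_that("home-island exclusion zeroes island cells only", {
  f <- mk_conc_fit(18, 1.45)
  roost <- bf_ls$roosts$colony1
  r0 <- pdf_map(f, roost, bf_ls, 1000)
  r1 <- pdf_map(f, roost, bf_ls, 1000, exclude_home_island = TRUE)
  isl <- matrix(is_on_home_island(rep(r0$x, times = length(r0$y)),
                                  rep(r0$y, each = length(r0$x)), bf_ls),
                nrow = length(r0$x))
  expect_true(all(r1$values[isl] == 0))
  expect_equal(r1$values[!isl], r0$values[!isl])
})

test_that("highest-density masks honour exact arithmetic and nesting", {
  ur <- structure(list(values = matrix(1, 10, 10), x = 1:10, y = 1:10,
                       cell_size = 1), class = "bat_raster")
  expect_equal(sum(contour_mask(ur, 0.95)), 95)
  sr <- ur; sr$values[] <- 0; sr$values[3, 4] <- 5
  m <- contour_mask(sr, 0.95)
  expect_equal(sum(m), 1)
  expect_true(m[3, 4])
  g <- ur; g$values <- outer(stats::dnorm(1:10, 5, 2), stats::dnorm(1:10, 5, 2))
  expect_lt(sum(contour_mask(g, 0.95)), sum(contour_mask(g, 0.99)))
})

test_that("overlap percentages satisfy the defining identities", {
  ur <- structure(list(values = matrix(1, 10, 10), x = 1:10, y = 1:10,
                       cell_size = 1), class = "bat_raster")
  A <- matrix(FALSE, 10, 10); A[1:5, 1:4] <- TRUE
  B <- matrix(FALSE, 10, 10); B[1:5, 1:8] <- TRUE    # A is the left half of B
  D <- matrix(FALSE, 10, 10); D[8:10, 8:10] <- TRUE
  expect_equal(overlap_percentage(A, A, ur), c(a_in_b = 100, b_in_a = 100))
  expect_equal(overlap_percentage(A, D, ur), c(a_in_b = 0, b_in_a = 0))
  expect_equal(overlap_percentage(A, B, ur), c(a_in_b = 100, b_in_a = 50))
  expect_error(overlap_percentage(A, matrix(FALSE, 10, 10), ur), "undefined")
  expect_error(overlap_percentage(A, matrix(TRUE, 5, 5), ur), "same grid")
})

test_that("land clipping restricts overlaps to land cells", {
  f1 <- mk_conc_fit(20, 1.45); f2 <- mk_conc_fit(20, 1.2)
  r1 <- pdf_map(f1, bf_ls$roosts$colony1, bf_ls, 1000)
  r2 <- pdf_map(f2, bf_ls$roosts$colony2, bf_ls, 1000)
  m1 <- contour_mask(r1); m2 <- contour_mask(r2)
  ov <- overlap_percentage(m1, m2, r1, bf_ls)
  expect_true(all(ov >= 0 & ov <= 100))
})
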