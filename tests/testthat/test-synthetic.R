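bf_eff <- list(individual_id = "b1", angle_mean = 1.2, distance_mean = 22)

test_that("simulated nights are reproducible and structurally valid", {
  sc <- colony_scenario("colony1", "dry")
  a <- simulate_night(sc, movement_kernel(), bf_eff, seed = 42, ls = bf_ls)
  b <- simulate_night(sc, movement_kernel(), bf_eff, seed = 42, ls = bf_ls)
  expect_identical(a$fixes, b$fixes)
  tru <- attr(a, "truth")
  expect_true(is_on_land(tru$anchor[1], tru$anchor[2], bf_ls))
  expect_false(is_on_home_island(tru$anchor[1], tru$anchor[2], bf_ls))
  roost <- bf_ls$roosts$colony1
  d0 <- sqrt(sum((unlist(a$fixes[1, c("x", "y")]) - roost)^2))
  dn <- sqrt(sum((unlist(a$fixes[nrow(a$fixes), c("x", "y")]) - roost)^2))
  expect_lt(d0, 500); expect_lt(dn, 500)
  expect_setequal(unique(tru$states), c(1L, 2L))
})

test_that("clean tracks stay under the speed filter so preprocessing is a no-op", {
  sc <- colony_scenario("colony1", "dry")
  for (s in 1:5) {
    tr <- simulate_night(sc, movement_kernel(), bf_eff, seed = s, ls = bf_ls)
    expect_lt(max(tr$fixes$speed, na.rm = TRUE), 15)
    cl <- remove_outliers(tr, bf_ls)
    expect_identical(cl$fixes, tr$fixes)
  }
})

test_that("degenerate variances give identical night bearings", {
  sc <- colony_scenario("colony1", "dry", commute_angle_sd = 0,
                        night_distance_sd = 0)
  br <- vapply(1:4, function(s)
    attr(simulate_night(sc, movement_kernel(), bf_eff, seed = s,
                        ls = bf_ls), "truth")$bearing, 0)
  expect_equal(br, rep(bf_eff$angle_mean, 4))
})

test_that("wet scenarios spread night bearings more than dry ones", {
  eff <- list(individual_id = "b", angle_mean = 1.2, distance_mean = 22)
  bearing_sd <- function(season) {
    sc <- colony_scenario("colony1", season)
    circ_sd(vapply(1:25, function(s)
      attr(simulate_night(sc, movement_kernel(), eff, seed = s,
                          ls = bf_ls), "truth")$bearing, 0))
  }
  expect_lt(bearing_sd("dry"), bearing_sd("wet"))
})

test_that("fix dropout is binomial at the configured rate", {
  sc <- colony_scenario("colony1", "dry")
  kept <- vapply(1:6, function(s) {
    tr <- simulate_night(sc, movement_kernel(), bf_eff, seed = s, ls = bf_ls,
                         corruptions = list(dropout = 0.2, speed_spikes = 0,
                                            water_strays = 0))
    nrow(tr$fixes)
  }, 0L)
  # interior slots drop independently with p = 0.2: mean within binomial bounds
  expect_gt(mean(kept), 360 * 0.8 - 3 * sqrt(360 * 0.2 * 0.8))
  expect_lt(mean(kept), 360 * 0.8 + 2 + 3 * sqrt(360 * 0.2 * 0.8))
})

test_that("datasets count out and are byte-identical under one seed", {
  scs <- list(colony_scenario("colony1", "dry", n_individuals = 2,
                              nights_per_individual = 2),
              colony_scenario("colony3", "dry", n_individuals = 2,
                              nights_per_individual = 2,
                              commute_angle_mean = 0.15,
                              mean_commute_distance = 17))
  d1 <- simulate_dataset(scs, movement_kernel(), bf_ls, seed = 9)
  d2 <- simulate_dataset(scs, movement_kernel(), bf_ls, seed = 9)
  expect_length(d1$tracks, 8)
  expect_equal(nrow(d1$truth$nights), 8)
  expect_equal(nrow(d1$truth$individuals), 4)
  expect_identical(d1$truth, d2$truth)
})

test_that("between-individual angular spread matches the generator parameter", {
  # law of large numbers on the truth table at n = 100 individuals
  sc <- colony_scenario("colony1", "dry", n_individuals = 100,
                        nights_per_individual = 1,
                        individual_angle_sd = 0.3,
                        commute_angle_mean = 1.45,
                        mean_commute_distance = 23,
                        individual_distance_sd = 1)
  d <- simulate_dataset(list(sc), movement_kernel(), bf_ls, seed = 31)
  expect_equal(nrow(d$truth$individuals), 100)
  expect_equal(stats::sd(d$truth$individuals$true_angle_mean), 0.3,
               tolerance = 0.22)
})
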