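test_that("the sequential speed filter removes only implausible fixes", {
  # middle fix implies 20 m/s in both directions at a 120 s interval
  tr <- make_track(x = c(0, 2400, 1200), y = c(0, 0, 0))
  cl <- remove_outliers(tr)
  expect_equal(nrow(cl$fixes), 2)
  expect_equal(cl$fixes$x, c(0, 1200))
  expect_equal(attr(cl, "removal_log")$reason, "speed")
  # all speeds admissible: identity
  tr2 <- make_track(x = c(0, 1200, 2400), y = c(0, 0, 0))
  cl2 <- remove_outliers(tr2)
  expect_equal(nrow(cl2$fixes), 3)
  expect_equal(nrow(attr(cl2, "removal_log")), 0)
})

test_that("over-water fixes beyond the range limit are removed with reason", {
  roost <- bf_ls$roosts$colony1
  # a slow track with one fix 70 km from the roost over open water
  far <- roost + c(0, 70000)
  expect_false(is_on_land(far[1], far[2], bf_ls))
  tr <- make_track(x = c(roost[1], far[1], roost[1] + 100),
                   y = c(roost[2], far[2], roost[2]), interval = 7200)
  cl <- remove_outliers(tr, bf_ls, max_range_km = 60)
  expect_equal(nrow(cl$fixes), 2)
  expect_true("water_range" %in% attr(cl, "removal_log")$reason)
})

test_that("outlier removal is idempotent", {
  sc <- colony_scenario("colony1", "dry")
  tr <- simulate_night(sc, movement_kernel(),
                       list(individual_id = "b", angle_mean = 1.2,
                            distance_mean = 22), seed = 8, ls = bf_ls,
                       corruptions = list(dropout = 0.1, speed_spikes = 3,
                                          water_strays = 2))
  once <- remove_outliers(tr, bf_ls)
  twice <- remove_outliers(once, bf_ls)
  expect_identical(once$fixes, twice$fixes)
})

test_that("injected corruptions are removed and clean fixes kept", {
  sc <- colony_scenario("colony1", "dry")
  tr <- simulate_night(sc, movement_kernel(),
                       list(individual_id = "b", angle_mean = 1.2,
                            distance_mean = 22), seed = 12, ls = bf_ls,
                       corruptions = list(dropout = 0, speed_spikes = 4,
                                          water_strays = 2))
  tru <- attr(tr, "truth")
  log <- attr(remove_outliers(tr, bf_ls), "removal_log")
  bad <- c(tru$spike_times, tru$stray_times)
  expect_true(all(bad %in% log$time))          # recall = 1
  expect_true(all(log$time %in% bad))          # precision = 1
})

test_that("downsampling keeps every k-th fix for exact divisors", {
  tr <- make_track(x = seq(0, 3000, by = 100), y = 0, interval = 30)
  ds <- downsample(tr, 120)
  expect_equal(ds$fixes$x, seq(0, 3000, by = 400))
  # already on target: identity
  tr2 <- make_track(x = 1:5 * 500, y = 0, interval = 120)
  expect_equal(downsample(tr2, 120)$fixes$x, tr2$fixes$x)
  # native coarser than target: pass-through with warning
  tr3 <- make_track(x = 1:5 * 500, y = 0, interval = 300)
  expect_warning(ds3 <- downsample(tr3, 120), "exceeds target")
  expect_equal(nrow(ds3$fixes), 5)
})

test_that("jittered fixes land within half an interval of the grid", {
  set.seed(3)
  t0 <- as.POSIXct("2022-03-01 23:00:00", tz = "UTC")
  times <- t0 + cumsum(stats::runif(120, 25, 35))
  fx <- data.frame(time = times, lon = NA_real_, lat = NA_real_,
                   x = seq_along(times) * 50, y = 0, speed = NA_real_)
  tr <- batforage:::new_track("t", "colony1", "dry", "p",
                              as.Date("2022-03-01"), fx)
  ds <- downsample(tr, 120)
  t0s <- as.numeric(ds$fixes$time[1])
  off <- (as.numeric(ds$fixes$time) - t0s) %% 120
  expect_true(all(pmin(off, 120 - off) <= 60))
  expect_false(any(duplicated(ds$fixes$time)))
})

test_that("regularization inserts missing slots and fixed-convention angles", {
  # a 6-minute gap at 2-minute intervals leaves 2 missing slots
  t0 <- as.POSIXct("2022-03-01 23:00:00", tz = "UTC")
  times <- t0 + c(0, 120, 240, 600, 720)
  fx <- data.frame(time = times, lon = NA_real_, lat = NA_real_,
                   x = c(0, 100, 200, 500, 600), y = 0, speed = NA_real_)
  tr <- batforage:::new_track("t", "colony1", "dry", "p",
                              as.Date("2022-03-01"), fx, interval = 120)
  ss <- regularize(tr)
  expect_equal(nrow(ss), 7)
  expect_equal(sum(!ss$obs), 2)
  # collinear equal-spaced fixes: all defined turning angles are 0
  ss2 <- regularize(make_track(x = 0:9 * 100, y = 0))
  expect_equal(ss2$angle[2:9], rep(0, 8))
  # square path, 90-degree left turns: +pi/2 (counterclockwise positive)
  ss3 <- regularize(make_track(x = c(0, 100, 100, 0, 0),
                               y = c(0, 0, 100, 100, 0)))
  expect_equal(ss3$angle[2:4], rep(pi / 2, 3))
  expect_error(regularize(make_track(x = c(0, 1), y = c(0, 0))),
               "insufficient-data")
})

test_that("night completeness requires both commutes and real displacement", {
  roost <- c(0, 0)
  full <- make_track(x = c(0, 5000, 10000, 5000, 100), y = 0)
  expect_equal(classify_night(full, roost), "complete")
  truncated <- make_track(x = c(0, 5000, 10000), y = 0)
  expect_equal(classify_night(truncated, roost), "incomplete")
  never_left <- make_track(x = c(0, 100, 200, 0), y = 0)
  expect_equal(classify_night(never_left, roost), "incomplete")
})
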