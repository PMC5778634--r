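test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_distance(51.05, 3.72, 51.05, 3.72), 0)
  ## meridian arc: R * dphi = 6371000 * 0.01 * pi / 180
  expect_equal(haversine_distance(0, 0, 0.01, 0), 1111.949, tolerance = 1e-6)
  set.seed(31)
  la <- runif(20, -80, 80); lo <- runif(20, -170, 170)
  lb <- la + rnorm(20, 0, 0.5); ob <- lo + rnorm(20, 0, 0.5)
  expect_equal(haversine_distance(la, lo, lb, ob),
               haversine_distance(lb, ob, la, lo))
  ## independent geodesic routine on the same sphere radius
  d_ref <- geosphere::distHaversine(cbind(lo, la), cbind(ob, lb), r = 6371000)
  expect_equal(haversine_distance(la, lo, lb, ob), d_ref, tolerance = 1e-9)
  expect_error(haversine_distance(95, 0, 0, 0), "out of range")
})

test_that("speed computation uses the actual gap", {
  expect_equal(compute_speed(0, 0, 0, 83.33 / 111194.93, 30), 10,
               tolerance = 1e-3)
  expect_equal(compute_speed(51, 3.7, 51, 3.7, 30), 0)
  expect_error(compute_speed(0, 0, 1, 1, 0), "time gap")
})

test_that("movement bands partition speeds at the stated boundaries", {
  sp <- c(0, 0.99, 1.0, 5, 9.99, 10.0, 20, 24.99, 25.0, 80, NA)
  expect_equal(as.character(classify_movement(sp)),
               c("stationary", "stationary", "pedestrian", "pedestrian",
                 "pedestrian", "bicycle", "bicycle", "bicycle", "motorized",
                 "motorized", "stationary"))
})

test_that("stream alignment attaches the two count epochs per fix and keeps orphans", {
  gps <- make_gps(lat = rep(51.05, 3), lon = rep(3.72, 3))
  cnt <- make_counts(c(10, 20, 30, 40, 50, 60))
  fused <- align_streams(gps, flag_wear(cnt))
  expect_equal(nrow(fused), 3)
  expect_equal(fused$counts_30s, c(30, 70, 110))
  expect_equal(fused$n_counts, c(2L, 2L, 2L))

  ## drop one count epoch -> partial fused epoch
  fused <- align_streams(gps, flag_wear(cnt[-2, ]))
  expect_equal(fused$n_counts[1], 1L)

  ## counts during GPS dropout become location-missing epochs
  fused <- align_streams(gps[-2, ], flag_wear(cnt))
  miss <- fused[!fused$located, ]
  expect_equal(nrow(miss), 1)
  expect_equal(miss$counts_30s, 70)
  expect_equal(sum(fused$n_counts), 6)
})

test_that("implausible fixes are flagged by each of the three thresholds", {
  ## 1100 m jump in 30 s: invalid by speed and distance
  g <- make_gps(lat = c(51, 51, 51 + 1100 / 111194.93, 51),
                lon = rep(3.7, 4))
  cnt <- make_counts(rep(100, 8))
  f <- flag_invalid_fixes(align_streams(g, flag_wear(cnt)))
  expect_equal(f$valid_fix, c(TRUE, TRUE, FALSE, TRUE))

  ## 900 m jump (108 km/h), flat: valid
  g <- make_gps(lat = c(51, 51 + 900 / 111194.93), lon = rep(3.7, 2))
  f <- flag_invalid_fixes(align_streams(g, flag_wear(make_counts(rep(1, 4)))))
  expect_true(all(f$valid_fix))

  ## 101 m elevation change over 10 m ground distance: invalid
  g <- make_gps(lat = c(51, 51 + 10 / 111194.93), lon = rep(3.7, 2),
                elev = c(10, 111))
  f <- flag_invalid_fixes(align_streams(g, flag_wear(make_counts(rep(1, 4)))))
  expect_equal(f$valid_fix, c(TRUE, FALSE))

  ## missing elevation skips the elevation test
  g$elevation_m <- c(NA, 111)
  f <- flag_invalid_fixes(align_streams(g, flag_wear(make_counts(rep(1, 4)))))
  expect_true(all(f$valid_fix))
})

test_that("plausibility filtering agrees with the brute-force oracle on random tracks", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    lat <- 51 + cumsum(rnorm(n, 0, 0.002))
    lon <- 3.7 + cumsum(rnorm(n, 0, 0.002))
    elev <- cumsum(rnorm(n, 0, 40))
    ## occasional extreme jump
    if (runif(1) < 0.5) {
      j <- sample(2:n, 1); lat[j] <- lat[j] + 0.02
    }
    g <- make_gps(lat, lon, elev)
    cnt <- make_counts(rep(100, 2 * n))
    f <- flag_invalid_fixes(align_streams(g, flag_wear(cnt)))
    expect_equal(f$valid_fix,
                 oracle_valid_flags(lat, lon, elev, g$timestamp),
                 tolerance = 0)
  }
})

test_that("invalidating a fix never changes wear or intensity totals", {
  set.seed(5)
  n <- 40
  lat <- 51 + cumsum(rnorm(n, 0, 0.003)); lon <- rep(3.7, n)
  g <- make_gps(lat, lon)
  cnt <- flag_wear(make_counts(sample(0:4000, 2 * n, TRUE)))
  f <- flag_invalid_fixes(align_streams(g, cnt))
  worn_min <- function(fu) sum(c(fu$worn1, fu$worn2), na.rm = TRUE) * 0.25
  f_all_valid <- align_streams(g, cnt)
  expect_equal(worn_min(f), worn_min(f_all_valid))
  expect_equal(table(c(as.character(f$intensity1), as.character(f$intensity2))),
               table(c(as.character(f_all_valid$intensity1),
                       as.character(f_all_valid$intensity2))))
})

test_that("single-epoch movement flicker is absorbed; corrections overwrite windows", {
  mv <- factor(c("pedestrian", "pedestrian", "bicycle", "pedestrian",
                 "pedestrian"), levels = posuse:::MOVEMENT_LEVELS)
  expect_equal(as.character(smooth_movement(mv)), rep("pedestrian", 5))
  mv2 <- factor(c("pedestrian", "bicycle", "bicycle", "pedestrian"),
                levels = posuse:::MOVEMENT_LEVELS)
  expect_equal(as.character(smooth_movement(mv2)), as.character(mv2))

  ## congested bus: a 12 km/h run declared motorized
  n <- 10
  step <- 12 / 3.6 * 30 / 111194.93  # 12 km/h in degrees latitude per 30 s
  g <- make_gps(lat = 51 + (0:(n - 1)) * step, lon = rep(3.7, n))
  f <- add_movement(flag_invalid_fixes(align_streams(
    g, flag_wear(make_counts(rep(50, 2 * n))))))
  expect_true(all(as.character(f$movement[-1]) == "bicycle"))
  corr <- data.frame(participant_id = "P1",
                     start = g$timestamp[1], end = g$timestamp[n] + 30,
                     movement = "motorized", stringsAsFactors = FALSE)
  fc <- apply_corrections(f, corr)
  expect_true(all(as.character(fc$movement) == "motorized"))
  expect_identical(apply_corrections(f, corr[0, ]), f)
  ## overlapping corrections: later row wins with a warning
  corr2 <- rbind(corr, transform(corr, movement = "pedestrian"))
  expect_warning(fc2 <- apply_corrections(f, corr2), "later row wins")
  expect_true(all(as.character(fc2$movement) == "pedestrian"))
})
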