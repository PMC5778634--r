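## fixture: one participant, home and school 1 km apart, Monday timetable
domain_fixture <- function() {
  sch_lat <- 51.05; sch_lon <- 3.72
  home_lat <- 51.06; home_lon <- 3.72
  cohort <- data.frame(participant_id = "P1", age = 14, gender = "male",
                       ethnicity = "western-European", education = "general",
                       ses = "high", sport_club = "yes", residence = "urban",
                       home_lat = home_lat, home_lon = home_lon,
                       school_id = "S1", class_id = "S1_C1",
                       stringsAsFactors = FALSE)
  schools <- data.frame(school_id = "S1", lat = sch_lat, lon = sch_lon,
                        stringsAsFactors = FALSE)
  tt <- data.frame(school_id = "S1", class_id = "S1_C1", weekday = 1,
                   kind = c("school", "recess", "pe"),
                   start = c("08:30", "10:10", "13:30"),
                   end = c("15:30", "10:25", "15:30"),
                   stringsAsFactors = FALSE)
  tt$start_min <- c(510, 610, 810); tt$end_min <- c(930, 625, 930)
  list(cohort = cohort, schools = schools, timetables = tt,
       sch = c(sch_lat, sch_lon), home = c(home_lat, home_lon))
}

fuse_at <- function(lat, lon, times, fx) {
  g <- data.frame(participant_id = "P1", timestamp = times, lat = lat,
                  lon = lon, elevation_m = 10, stringsAsFactors = FALSE)
  cnt <- data.frame(participant_id = "P1",
                    timestamp = sort(c(times, times + 15)),
                    counts = 50L, worn = TRUE, stringsAsFactors = FALSE)
  f <- add_movement(flag_invalid_fixes(align_streams(g, cnt)))
  assign_domain(f, fx$cohort, fx$schools, fx$timetables)
}

test_that("school, home and leisure assignment follows buffers and timetables", {
  fx <- domain_fixture()
  ## 2015-09-14 is a Monday
  deg50 <- 50 / 111194.93
  t_class <- ts0(10, 0)   # inside school hours, no block
  t_recess <- ts0(10, 15)
  t_pe <- ts0(14, 0)
  t_evening <- ts0(20, 0)
  f <- fuse_at(rep(fx$sch[1] + deg50, 4), rep(fx$sch[2], 4),
               c(t_class, t_recess, t_pe, t_evening), fx)
  expect_equal(as.character(f$domain),
               c("school_class", "school_recess", "school_pe", "leisure"))

  ## weekend: same place, school hours do not apply
  f <- fuse_at(fx$sch[1] + deg50, fx$sch[2], ts0(10, 0, date = "2015-09-19"),
               fx)
  expect_equal(as.character(f$domain), "leisure")

  ## home buffer boundary: 99.9 m in, 100.1 m out
  d1 <- 99.9 / 111194.93; d2 <- 100.1 / 111194.93
  f <- fuse_at(c(fx$home[1] + d1, fx$home[1] + d2), rep(fx$home[2], 2),
               c(ts0(18, 0), ts0(18, 0, 30)), fx)
  expect_equal(as.character(f$domain), c("home", "leisure"))
})

test_that("school subclasses only occur inside school hours on school days", {
  fx <- domain_fixture()
  cfg <- noise_free_config(n = 6, seed = 3)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim)
  sch <- res$fused[!is.na(res$fused$domain) &
                     startsWith(as.character(res$fused$domain), "school"), ]
  expect_true(all(posuse:::ts_weekday(posuse:::ts_date(sch$timestamp)) <= 5))
  tod <- posuse:::ts_tod_min(sch$timestamp)
  expect_true(all(tod >= 510 & tod < 930))
})

test_that("consolidation is run-length encoding with duration bookkeeping", {
  ## H H H L L H -> 3 segments of 1.5, 1.0, 0.5 min
  times <- ts0(18, 0) + (0:5) * 30
  f <- data.frame(participant_id = "P1", timestamp = times,
                  lat = 51, lon = 3.7, elevation_m = 10, located = TRUE,
                  counts1 = 50L, counts2 = 50L,
                  intensity1 = factor("sedentary",
                                      posuse:::INTENSITY_LEVELS),
                  intensity2 = factor("sedentary",
                                      posuse:::INTENSITY_LEVELS),
                  worn1 = TRUE, worn2 = TRUE, n_counts = 2L,
                  counts_30s = 100,
                  movement = factor("stationary",
                                    posuse:::MOVEMENT_LEVELS),
                  domain = factor(c("home", "home", "home", "leisure",
                                    "leisure", "home"),
                                  posuse:::DOMAIN_LEVELS),
                  stringsAsFactors = FALSE)
  segs <- consolidate(f)
  expect_equal(as.character(segs$label), c("home", "leisure", "home"))
  expect_equal(segs$duration_min, c(1.5, 1.0, 0.5))
  ## intensity minutes tile the durations (fully worn)
  expect_equal(segs$st_min, segs$duration_min)
  ## a location-missing epoch breaks runs
  f2 <- f; f2$domain[3] <- NA
  segs2 <- consolidate(f2)
  expect_equal(as.character(segs2$label), c("home", "leisure", "home"))
  expect_equal(segs2$duration_min, c(1.0, 1.0, 0.5))
})

test_that("a pedestrian run followed by a bicycle run makes two trips", {
  step_ped <- 5 / 3.6 * 30 / 111194.93
  step_bik <- 16 / 3.6 * 30 / 111194.93
  lat <- 51 + cumsum(c(0, rep(step_ped, 6), rep(step_bik, 6)))
  g <- make_gps(lat, rep(3.7, length(lat)))
  fx <- domain_fixture()
  cnt <- make_counts(rep(600, 2 * length(lat)))
  f <- add_movement(flag_invalid_fixes(align_streams(g, flag_wear(cnt))))
  f <- assign_domain(f, fx$cohort, fx$schools, fx$timetables)
  segs <- consolidate(f)
  trips <- segs[segs$kind == "trip", ]
  expect_equal(as.character(trips$label), c("pedestrian", "bicycle"))
})

test_that("annotation join uses maximal overlap with tie to the earlier event", {
  s <- rbind(make_segment("P1", "2015-09-14", "event", "leisure", 900, 40),
             make_segment("P1", "2015-09-14", "trip", "bicycle", 940, 10),
             make_segment("P1", "2015-09-14", "event", "leisure", 950, 40))
  midnight <- as.POSIXct("2015-09-14 00:00:00", tz = "UTC")
  ann <- data.frame(participant_id = "P1",
                    start = midnight + 905 * 60, end = midnight + 935 * 60,
                    pos_category = "park", company = "alone",
                    reasons = "habit", activities = "walking",
                    stringsAsFactors = FALSE)
  out <- join_annotations(s, ann)
  expect_equal(out$pos_category, c("park", NA, NA))

  ## greedy maximal overlap equals brute-force optimum on a two-event case
  ann2 <- rbind(ann, transform(ann, start = midnight + 955 * 60,
                               end = midnight + 985 * 60,
                               pos_category = "square"))
  out2 <- join_annotations(s, ann2)
  expect_equal(out2$pos_category, c("park", NA, "square"))

  ## tie: annotation overlapping both events equally goes to the earlier
  ann3 <- ann
  ann3$start <- midnight + 930 * 60; ann3$end <- midnight + 960 * 60
  expect_warning(out3 <- join_annotations(s, ann3), "tie")
  expect_equal(out3$pos_category, c("park", NA, NA))

  ## zero overlap -> warning, unused
  ann4 <- ann; ann4$start <- midnight + 400 * 60; ann4$end <- midnight + 420 * 60
  expect_warning(out4 <- join_annotations(s, ann4), "overlaps no leisure event")
  expect_true(all(is.na(out4$pos_category)))
})

test_that("segment boundaries match ground-truth transitions within one epoch", {
  cfg <- noise_free_config(n = 8, seed = 19)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim)
  truth <- sim$truth$segments
  segs <- res$segments
  ## every true POS dwell appears as a leisure event within +/- 30 s
  pos <- truth[!is.na(truth$pos_category), ]
  for (i in seq_len(nrow(pos))) {
    cand <- segs[segs$participant_id == pos$participant_id[i] &
                   segs$kind == "event" & segs$label == "leisure" &
                   abs(as.numeric(segs$start - pos$start[i], units = "secs")) <= 30 &
                   abs(as.numeric(segs$end - pos$end[i], units = "secs")) <= 30, ]
    expect_equal(nrow(cand), 1)
  }
})
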