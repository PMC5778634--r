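test_that("a trip to a POS and the trip home are both attributed (park by bike)", {
  s <- rbind(
    make_segment("P1", "2015-09-14", "event", "home", 900, 30),
    make_segment("P1", "2015-09-14", "trip", "bicycle", 930, 10, mpa = 8),
    make_segment("P1", "2015-09-14", "event", "leisure", 940, 30,
                 pos_category = "park", company = "friends/classmates",
                 lpa = 20, mpa = 5),
    make_segment("P1", "2015-09-14", "trip", "bicycle", 970, 12, mpa = 9),
    make_segment("P1", "2015-09-14", "event", "home", 982, 60))
  v <- extract_pos_visits(s)
  expect_equal(nrow(v), 1)
  expect_equal(v$total_min, 10 + 30 + 12)
  expect_equal(v$inbound_min, 10)
  expect_equal(v$outbound_min, 12)
  expect_equal(v$mvpa_min, 8 + 5 + 9)
})

test_that("a trip between home and school is never POS exposure", {
  ## cycling through a park on the way to school: no POS event adjacent
  s <- rbind(
    make_segment("P1", "2015-09-14", "event", "home", 450, 40),
    make_segment("P1", "2015-09-14", "trip", "bicycle", 490, 20),
    make_segment("P1", "2015-09-14", "event", "school_class", 510, 420))
  v <- extract_pos_visits(s)
  expect_equal(nrow(v), 0)
  ## same for an unannotated leisure stop
  s2 <- rbind(
    make_segment("P1", "2015-09-14", "trip", "pedestrian", 900, 10),
    make_segment("P1", "2015-09-14", "event", "leisure", 910, 30),
    make_segment("P1", "2015-09-14", "trip", "pedestrian", 940, 10))
  expect_equal(nrow(extract_pos_visits(s2)), 0)
})

test_that("a trip bridging two POS events is counted exactly once", {
  s <- rbind(
    make_segment("P1", "2015-09-14", "trip", "pedestrian", 890, 10),
    make_segment("P1", "2015-09-14", "event", "leisure", 900, 30,
                 pos_category = "park", company = "alone"),
    make_segment("P1", "2015-09-14", "trip", "pedestrian", 930, 8),
    make_segment("P1", "2015-09-14", "event", "leisure", 938, 20,
                 pos_category = "square", company = "alone"),
    make_segment("P1", "2015-09-14", "trip", "bicycle", 958, 12),
    make_segment("P1", "2015-09-14", "event", "home", 970, 30))
  v <- extract_pos_visits(s)
  expect_equal(nrow(v), 2)
  ## bridge (8 min) is outbound of the park visit, not inbound of the square
  expect_equal(v$outbound_min[1], 8)
  expect_equal(v$inbound_min[2], 0)
  ## conservation: total visit minutes = dwells + each trip once
  expect_equal(sum(v$total_min), 10 + 30 + 8 + 20 + 12)
})

test_that("participant summaries average over valid days and count company", {
  v <- rbind(
    data.frame(participant_id = "A", date = as.Date("2015-09-14"),
               pos_category = "park", company = "friends/classmates|siblings/cousins",
               reasons = "habit", activities = "walking",
               total_min = 40, st_min = 10, lpa_min = 20, mpa_min = 8,
               vpa_min = 2, mvpa_min = 10, stringsAsFactors = FALSE))
  ep <- make_counts(rep(c(300, 3000), 2 * 600), pid = "A", start = ts0(8, 0))
  ep$worn <- TRUE
  wear <- select_valid(data.frame(
    participant_id = c("A", "A"), date = as.Date("2015-09-14") + 0:1,
    wear_min = c(600, 560)))
  cohort <- data.frame(participant_id = "A", age = 14, gender = "female",
                       ethnicity = "western-European", education = "general",
                       ses = "high", sport_club = "no", residence = "urban",
                       home_lat = 51, home_lon = 3.7, school_id = "S1",
                       class_id = "S1_C1", stringsAsFactors = FALSE)
  sm <- summarize_participants(v, ep, wear, cohort)
  expect_equal(sm$n_days, 2)
  expect_equal(sm$pos_min_day, 20)      # {40, 0} over two valid days
  expect_true(sm$used_pos)
  expect_equal(sm$visits_friends, 1)
  expect_equal(sm$visits_siblings, 1)
  expect_equal(sm$visits_parents, 0)
  ## POS MVPA never exceeds total MVPA
  expect_lte(sm$pos_mvpa_min_day, sm$mvpa_min_day)

  ## no visits -> used_pos FALSE, all POS outcomes 0
  sm0 <- summarize_participants(posuse:::empty_visits(), ep, wear, cohort)
  expect_false(sm0$used_pos)
  expect_equal(sm0$pos_min_day, 0)
})

test_that("descriptives report user share and normalized category mix", {
  cfg <- noise_free_config(n = 12, seed = 29)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim)
  d <- res$descriptives
  expect_equal(d$pct_pos_users, mean(res$summaries$used_pos) * 100)
  expect_equal(sum(d$pct_by_category), 100, tolerance = 1e-9)
  expect_true(all(d$pct_by_company >= 0))
  ## deleting all annotations yields zero visits and no users
  sim2 <- sim
  sim2$annotations <- posuse:::empty_annotations()
  res2 <- run_pipeline(sim2)
  expect_equal(nrow(res2$visits), 0)
  expect_false(any(res2$summaries$used_pos))
})
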