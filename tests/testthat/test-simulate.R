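test_that("cohort generation honours cardinality, seeds and marginals", {
  cfg <- sim_config(n_participants = 40, n_schools = 6, seed = 9)
  ctx <- generate_cohort(cfg)
  expect_equal(nrow(ctx$schools), 6)
  expect_true(all(ctx$cohort$school_id %in% ctx$schools$school_id))
  ## determinism under a fixed seed
  ctx2 <- generate_cohort(cfg)
  expect_identical(ctx, ctx2)
  expect_error(generate_cohort(sim_config(n_participants = 0)),
               "at least one participant")
})

test_that("realized girl proportion sits in the binomial 99% interval at n = 10000", {
  cfg <- sim_config(n_participants = 10000, n_schools = 6, seed = 101)
  ctx <- generate_cohort(cfg)
  p_hat <- mean(ctx$cohort$gender == "female")
  ## 99% interval around the configured 0.544
  half <- qnorm(0.995) * sqrt(0.544 * 0.456 / 10000)
  expect_gt(p_hat, 0.544 - half)
  expect_lt(p_hat, 0.544 + half)
})

test_that("config validation rejects out-of-band speeds and bad probabilities", {
  expect_error(sim_config(behaviour = list(
    mode_speed_kmh = c(pedestrian = 5, bicycle = 26, motorized = 40))),
    "bicycle speed")
  expect_error(sim_config(behaviour = list(pos_visit_prob = 1.4)),
               "probabilities")
  expect_error(sim_config(behaviour = list(dwell_mean_min = -2)),
               "strictly positive")
})

test_that("zero visit probability yields zero POS ground truth and annotations", {
  cfg <- noise_free_config(n = 5, seed = 13,
                           behaviour = list(pos_visit_prob = 0))
  expect_error(cfg, NA)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$annotations), 0)
  expect_true(all(sim$truth$days$pos_min == 0))
})

test_that("generated trips travel at the configured mode speed inside its band", {
  cfg <- noise_free_config(n = 8, seed = 21)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$segments
  trips <- tr[tr$domain == "transport" & !is.na(tr$mode), ]
  gps <- sim$gps
  for (i in seq_len(nrow(trips))) {
    sel <- gps$participant_id == trips$participant_id[i] &
      gps$timestamp >= trips$start[i] & gps$timestamp < trips$end[i]
    g <- gps[sel, ]
    if (nrow(g) < 3) next
    d <- haversine_distance(g$lat[-nrow(g)], g$lon[-nrow(g)],
                            g$lat[-1], g$lon[-1])
    v <- mean(d) / 30 * 3.6
    band <- switch(trips$mode[i], pedestrian = c(1, 10),
                   bicycle = c(10, 25), motorized = c(25, 130))
    expect_gte(v, band[1])
    expect_lt(v, band[2])
  }
})

test_that("ground-truth segments tile each simulated day without overlap", {
  cfg <- sim_config(n_participants = 6, n_schools = 3, seed = 33)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$segments
  key <- paste(tr$participant_id, tr$date)
  for (k in unique(key)) {
    d <- tr[key == k, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] == d$end[-nrow(d)]))
  }
})

test_that("injected non-wear runs are recovered exactly by detect_nonwear", {
  cfg <- sim_config(n_participants = 10, n_schools = 3, seed = 55,
                    behaviour = list(nonwear_prob = 1, dropout_prob = 0))
  sim <- simulate_dataset(cfg)
  td <- sim$truth$days
  cnt <- sim$counts
  for (i in seq_len(nrow(td))) {
    sel <- cnt$participant_id == td$participant_id[i] &
      posuse:::ts_date(cnt$timestamp) == td$date[i]
    segs <- detect_nonwear(cnt$timestamp[sel], cnt$counts[sel])
    nw <- segs[segs$status == "non-wear", ]
    expect_equal(nrow(nw), 1)
    expect_equal(posuse:::ts_tod_min(nw$start), td$nonwear_start[i])
    expect_equal(posuse:::ts_tod_min(nw$end), td$nonwear_end[i])
  }
})

test_that("raising an occurrence coefficient raises that stratum's user share", {
  base <- c(gender_female = 0)
  strong <- c(gender_female = 2)
  share <- function(beta, seed) {
    d <- simulate_hurdle_data(n = 4000, beta_occ = beta,
                              beta_amt = c(gender_female = 0),
                              school_sigma = 0, seed = seed)
    mean(d$used_pos[d$gender == "female"])
  }
  expect_gt(share(strong, 71), share(base, 71))
})

test_that("dataset write emits row counts consistent with the generator", {
  cfg <- noise_free_config(n = 10, seed = 43)
  sim <- simulate_dataset(cfg)
  ## counts rows = 2 x gps rows when there is no dropout
  expect_equal(nrow(sim$counts), 2 * nrow(sim$gps))
  ## every fix timestamp has its two count timestamps at +0 and +15 s
  ckey <- paste(sim$counts$participant_id, as.numeric(sim$counts$timestamp))
  expect_true(all(paste(sim$gps$participant_id,
                        as.numeric(sim$gps$timestamp)) %in% ckey))
  expect_true(all(paste(sim$gps$participant_id,
                        as.numeric(sim$gps$timestamp) + 15) %in% ckey))
})
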