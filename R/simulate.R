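## Synthetic cohort generator. Every downstream stage gets a known-answer
## surface: the generator records, per participant-day, the true sequence
## of domains, modes and POS visits alongside the emitted GPS fixes (30 s),
## count epochs (15 s) and interview-style annotations.

#' Generate the cohort, school and timetable tables
#'
#' Schools receive coordinates in the study area and three classes each;
#' classes share school hours (Mon--Fri 08:30--15:30) with two recess
#' blocks and one weekly two-hour PE block whose weekday rotates by class.
#' Participants draw demographics from the configured marginals, a home
#' coordinate 0.3--2.5 km from their school, and school-level random
#' intercepts for the POS occurrence and amount processes.
#'
#' @param config \code{\link{sim_config}}
#' @return list: cohort, schools, timetables, pos_sites, school_effects
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(derive_seed(config$seed, 0))
  area <- config$study_area
  k <- config$n_schools
  schools <- data.frame(
    school_id = sprintf("S%d", seq_len(k)),
    lat = runif(k, area[["lat_min"]] + 0.02, area[["lat_max"]] - 0.02),
    lon = runif(k, area[["lon_min"]] + 0.02, area[["lon_max"]] - 0.02),
    stringsAsFactors = FALSE)

  classes <- expand.grid(school = seq_len(k), cls = 1:3)
  tt <- list()
  for (i in seq_len(nrow(classes))) {
    sid <- sprintf("S%d", classes$school[i])
    cid <- sprintf("%s_C%d", sid, classes$cls[i])
    pe_day <- 1 + (i - 1) %% 5
    for (wd in 1:5) {
      tt[[length(tt) + 1]] <- data.frame(
        school_id = sid, class_id = cid, weekday = wd,
        kind = c("school", "recess", "recess", if (wd == pe_day) "pe"),
        start = c("08:30", "10:10", "12:00", if (wd == pe_day) "13:30"),
        end = c("15:30", "10:25", "12:50", if (wd == pe_day) "15:30"),
        stringsAsFactors = FALSE)
    }
  }
  timetables <- do.call(rbind, tt)
  hm <- function(x) as.numeric(substr(x, 1, 2)) * 60 + as.numeric(substr(x, 4, 5))
  timetables$start_min <- hm(timetables$start)
  timetables$end_min <- hm(timetables$end)

  n <- config$n_participants
  d <- config$demographics
  age <- pmin(d$age_range[2], pmax(d$age_range[1],
                                   rnorm(n, d$age_mean, d$age_sd)))
  school_idx <- rep_len(seq_len(k), n)
  cls <- sample(1:3, n, replace = TRUE)
  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = round(age, 1),
    gender = ifelse(runif(n) < d$p_girl, "female", "male"),
    ethnicity = ifelse(runif(n) < d$p_nonwestern, "non-western-European",
                       "western-European"),
    education = sample(names(d$education_probs), n, replace = TRUE,
                       prob = d$education_probs),
    ses = ifelse(runif(n) < d$p_low_ses, "low", "high"),
    sport_club = ifelse(runif(n) < d$p_sport_club, "yes", "no"),
    residence = sample(names(d$residence_probs), n, replace = TRUE,
                       prob = d$residence_probs),
    school_id = sprintf("S%d", school_idx),
    class_id = sprintf("S%d_C%d", school_idx, cls),
    stringsAsFactors = FALSE)

  ## homes: 0.3--2.5 km from the school, inside the study area
  sl <- schools$lat[school_idx]; so <- schools$lon[school_idx]
  home_lat <- home_lon <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      la <- sl[i] + runif(1, -0.020, 0.020)
      lo <- so[i] + runif(1, -0.030, 0.030)
      dist <- haversine_distance(la, lo, sl[i], so[i])
      if (dist >= 300 && dist <= 2500 &&
          la > area[["lat_min"]] && la < area[["lat_max"]] &&
          lo > area[["lon_min"]] && lo < area[["lon_max"]]) break
    }
    home_lat[i] <- la; home_lon[i] <- lo
  }
  cohort$home_lat <- home_lat; cohort$home_lon <- home_lon

  pos_sites <- data.frame(
    site_id = sprintf("POS%03d", seq_len(config$n_pos_sites)),
    category = sample(names(config$pos_category_probs), config$n_pos_sites,
                      replace = TRUE, prob = config$pos_category_probs),
    lat = runif(config$n_pos_sites, area[["lat_min"]], area[["lat_max"]]),
    lon = runif(config$n_pos_sites, area[["lon_min"]], area[["lon_max"]]),
    stringsAsFactors = FALSE)

  sg <- config$effects$school_sigma
  school_effects <- data.frame(
    school_id = schools$school_id,
    b_occ = rnorm(k, 0, sg), b_amt = rnorm(k, 0, sg),
    stringsAsFactors = FALSE)

  list(cohort = cohort, schools = schools, timetables = timetables,
       pos_sites = pos_sites, school_effects = school_effects)
}

## study dates: day 1 a Monday, day 2 the following Saturday, then the
## remaining weekdays/Sunday
study_dates <- function(config) {
  offs <- c(0, 5, 1, 6, 2, 3, 4)
  if (config$n_days > 7) offs <- c(offs, 7 + offs)[seq_len(config$n_days)]
  config$start_date + offs[seq_len(config$n_days)]
}

#' Generate one participant-day
#'
#' Builds the day's true schedule (home, trips, school blocks per the
#' timetable, optional POS visits with inbound/outbound trips) on a 30 s
#' grid, then emits GPS fixes every 30 s, counts every 15 s (two per fix
#' interval), an annotation row per POS dwell, and the ground truth.
#' Non-wear is injected as a zero-count run of at least 60 min; GPS
#' dropout as a window of deleted fixes.
#'
#' @param participant one cohort row
#' @param date the simulated date
#' @param ctx cohort context from \code{\link{generate_cohort}}
#' @param config \code{\link{sim_config}}
#' @param seed integer seed for this participant-day (derive from the
#'   master seed with the counter-based splitter)
#' @return list: gps, counts, annotations, truth_segments, truth_day
#' @export
generate_day <- function(participant, date, ctx, config, seed) {
  date <- as.Date(date)
  dates <- study_dates(config)
  if (!date %in% dates) stop_input("generate_day: date outside study window")
  set.seed(seed)
  b <- config$behaviour
  p <- participant
  x <- covariate_row(p, config$demographics$age_mean)
  se <- ctx$school_effects[ctx$school_effects$school_id == p$school_id, ]
  p_visit <- plogis(qlogis(b$pos_visit_prob) +
                    lin_pred(x, config$effects$occurrence) + se$b_occ)
  dwell_mean <- exp(log(b$dwell_mean_min) +
                    lin_pred(x, config$effects$amount) + se$b_amt)

  wd <- ts_weekday(date)
  school_day <- wd <= 5
  attr(p, "weekday") <- wd
  sched <- build_schedule(p, ctx, config, school_day, p_visit, dwell_mean)

  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  emit_day(sched, p, b, midnight, config)
}

## ---- schedule construction -------------------------------------------------

## a schedule is a data.frame of blocks tiling [wake, sleep) in minutes:
## context (count regime), domain, mode, pos_category, from/to coordinates
## (trips) or anchor coordinate (events)
sched_block <- function(context, domain, mode = NA_character_,
                        pos_category = NA_character_, start, end,
                        lat, lon, lat2 = NA_real_, lon2 = NA_real_,
                        site_id = NA_character_) {
  data.frame(context = context, domain = domain, mode = mode,
             pos_category = pos_category, start_min = start, end_min = end,
             lat = lat, lon = lon, lat2 = lat2, lon2 = lon2,
             site_id = site_id, stringsAsFactors = FALSE)
}

## round minutes up to the 30 s grid
grid_up <- function(m) ceiling(m * 2) / 2

trip_minutes <- function(dist_m, speed_kmh) {
  max(1, grid_up(dist_m / 1000 / speed_kmh * 60))
}

pick_mode <- function(b) sample(names(b$mode_probs), 1, prob = b$mode_probs)

## choose a POS site away from home, school and the current position (a
## chained visit must involve a real trip, not a zero-length hop)
pick_site <- function(ctx, p, from = NULL, max_km = 3) {
  s <- ctx$pos_sites
  d_home <- haversine_distance(s$lat, s$lon, p$home_lat, p$home_lon)
  sch <- ctx$schools[ctx$schools$school_id == p$school_id, ]
  d_sch <- haversine_distance(s$lat, s$lon, sch$lat, sch$lon)
  d_from <- if (is.null(from)) Inf else
    haversine_distance(s$lat, s$lon, from[1], from[2])
  ok <- d_home > 250 & d_sch > 250 & d_from > 300 & d_home <= max_km * 1000
  if (!any(ok)) ok <- d_home > 250 & d_sch > 250 & d_from > 300
  cand <- which(ok)
  cand[sample.int(length(cand), 1)]
}

build_schedule <- function(p, ctx, config, school_day, p_visit, dwell_mean) {
  b <- config$behaviour
  wake <- b$wake_min; sleep <- b$sleep_min
  sch <- ctx$schools[ctx$schools$school_id == p$school_id, ]
  home <- c(p$home_lat, p$home_lon)
  blocks <- list()
  if (school_day) {
    tt <- ctx$timetables[ctx$timetables$class_id == p$class_id, ]
    ## weekday of the schedule is resolved by the caller through `date`;
    ## school blocks for this weekday:
    wd <- attr(p, "weekday") %||% NA
    tt_day <- tt  # filtered by caller via attr; fall back to Monday
    if (!is.na(wd)) tt_day <- tt[tt$weekday == wd, ]
    sch_rows <- tt_day[tt_day$kind == "school", ]
    sch_start <- sch_rows$start_min[1]; sch_end <- sch_rows$end_min[1]
    d_hs <- haversine_distance(home[1], home[2], sch$lat, sch$lon)
    mode1 <- pick_mode(b)
    t1 <- trip_minutes(d_hs, b$mode_speed_kmh[[mode1]])
    dep <- sch_start - t1
    blocks[[length(blocks) + 1]] <-
      sched_block("home", "home", start = wake, end = dep,
                  lat = home[1], lon = home[2])
    blocks[[length(blocks) + 1]] <-
      sched_block(mode1, "transport", mode = mode1, start = dep,
                  end = sch_start, lat = home[1], lon = home[2],
                  lat2 = sch$lat, lon2 = sch$lon)
    ## decompose school hours into class / pe / recess blocks
    subs <- tt_day[tt_day$kind != "school", ]
    subs <- subs[order(subs$start_min), ]
    cur <- sch_start
    add_school <- function(ctxname, dom, s, e) {
      if (e > s) blocks[[length(blocks) + 1]] <<-
        sched_block(ctxname, dom, start = s, end = e, lat = sch$lat,
                    lon = sch$lon)
    }
    for (i in seq_len(nrow(subs))) {
      add_school("school_class", "school_class", cur, subs$start_min[i])
      ctxname <- if (subs$kind[i] == "pe") "school_pe" else "school_recess"
      add_school(ctxname, ctxname, subs$start_min[i], subs$end_min[i])
      cur <- subs$end_min[i]
    }
    add_school("school_class", "school_class", cur, sch_end)
    anchor_t <- sch_end
    anchor <- c(sch$lat, sch$lon)
  } else {
    anchor_t <- 840  # weekend visits depart at 14:00
    anchor <- home
  }

  visit <- runif(1) < p_visit
  n_vis <- if (visit) 1 + min(1, rpois(1, b$visits_extra_pois)) else 0
  if (!school_day && !visit) {
    blocks[[length(blocks) + 1]] <-
      sched_block("home", "home", start = wake, end = sleep,
                  lat = home[1], lon = home[2])
    return(finish_schedule(blocks))
  }
  if (!school_day && visit) {
    blocks[[length(blocks) + 1]] <-
      sched_block("home", "home", start = wake, end = anchor_t,
                  lat = home[1], lon = home[2])
  }

  t <- anchor_t
  if (n_vis > 0) {
    from <- anchor
    for (v in seq_len(n_vis)) {
      si <- pick_site(ctx, p, from = if (v > 1) from else NULL)
      site <- ctx$pos_sites[si, ]
      mode <- pick_mode(b)
      d <- haversine_distance(from[1], from[2], site$lat, site$lon)
      tm <- trip_minutes(d, b$mode_speed_kmh[[mode]])
      ## reserve return-trip time so the day always ends at home
      d_back <- haversine_distance(site$lat, site$lon, home[1], home[2])
      t_back <- trip_minutes(d_back, b$mode_speed_kmh[["bicycle"]])
      avail <- sleep - 5 - t - tm - t_back
      if (avail < 2.5) break
      dwell <- grid_up(rgamma(1, shape = b$dwell_shape,
                              rate = b$dwell_shape / dwell_mean))
      dwell <- min(max(2.5, dwell), avail)
      cat_active <- site$category %in% b$active_pos_categories
      blocks[[length(blocks) + 1]] <-
        sched_block(mode, "transport", mode = mode, start = t, end = t + tm,
                    lat = from[1], lon = from[2], lat2 = site$lat,
                    lon2 = site$lon)
      blocks[[length(blocks) + 1]] <-
        sched_block(if (cat_active) "pos_active" else "pos_sedentary",
                    "leisure", pos_category = site$category,
                    start = t + tm, end = t + tm + dwell,
                    lat = site$lat, lon = site$lon, site_id = site$site_id)
      t <- t + tm + dwell
      from <- c(site$lat, site$lon)
    }
    ## return home
    d <- haversine_distance(from[1], from[2], home[1], home[2])
    mode <- pick_mode(b)
    tm <- trip_minutes(d, b$mode_speed_kmh[[mode]])
    blocks[[length(blocks) + 1]] <-
      sched_block(mode, "transport", mode = mode, start = t, end = t + tm,
                  lat = from[1], lon = from[2], lat2 = home[1],
                  lon2 = home[2])
    t <- t + tm
  } else if (school_day) {
    ## straight home after school
    d <- haversine_distance(anchor[1], anchor[2], home[1], home[2])
    mode <- pick_mode(b)
    tm <- trip_minutes(d, b$mode_speed_kmh[[mode]])
    blocks[[length(blocks) + 1]] <-
      sched_block(mode, "transport", mode = mode, start = t, end = t + tm,
                  lat = anchor[1], lon = anchor[2], lat2 = home[1],
                  lon2 = home[2])
    t <- t + tm
  }
  blocks[[length(blocks) + 1]] <-
    sched_block("home", "home", start = t, end = sleep,
                lat = home[1], lon = home[2])
  finish_schedule(blocks)
}

finish_schedule <- function(blocks) {
  s <- do.call(rbind, blocks)
  s <- s[s$end_min > s$start_min, , drop = FALSE]
  stopifnot(all(abs(s$start_min[-1] - s$end_min[-nrow(s)]) < 1e-9))
  rownames(s) <- NULL
  s
}

## ---- emission --------------------------------------------------------------

emit_day <- function(sched, p, b, midnight, config) {
  wake <- sched$start_min[1]; sleep <- sched$end_min[nrow(sched)]
  fix_min <- seq(wake, sleep - 0.5, by = 0.5)          # 30 s grid
  cnt_min <- seq(wake, sleep - 0.25, by = 0.25)        # 15 s grid
  blk_fix <- findInterval(fix_min + 1e-9, sched$start_min)
  blk_cnt <- findInterval(cnt_min + 1e-9, sched$start_min)

  ## GPS positions
  lat <- sched$lat[blk_fix]; lon <- sched$lon[blk_fix]
  trip <- !is.na(sched$mode[blk_fix])
  if (any(trip)) {
    bi <- blk_fix[trip]
    frac <- (fix_min[trip] - sched$start_min[bi] + 0.5) /
      (sched$end_min[bi] - sched$start_min[bi])
    lat[trip] <- sched$lat[bi] + frac * (sched$lat2[bi] - sched$lat[bi])
    lon[trip] <- sched$lon[bi] + frac * (sched$lon2[bi] - sched$lon[bi])
  }
  jit <- b$gps_jitter_m / 111320
  lat <- lat + rnorm(length(lat), 0, jit)
  lon <- lon + rnorm(length(lon), 0, jit / cos(mean(lat) * pi / 180))
  gps <- data.frame(participant_id = p$participant_id,
                    timestamp = midnight + fix_min * 60,
                    lat = lat, lon = lon,
                    elevation_m = round(rnorm(length(lat), 10, 1), 1),
                    stringsAsFactors = FALSE)

  ## counts from context-conditional regimes
  ctx_cnt <- sched$context[blk_cnt]
  counts <- integer(length(cnt_min))
  for (cx in unique(ctx_cnt)) {
    i <- which(ctx_cnt == cx)
    w <- b$context_regimes[[cx]]
    reg <- sample(INTENSITY_LEVELS, length(i), replace = TRUE, prob = w)
    for (r in unique(reg)) {
      j <- i[reg == r]
      pr <- b$regime_lognormal[[r]]
      counts[j] <- as.integer(round(rlnorm(length(j), pr[["meanlog"]],
                                           pr[["sdlog"]])))
    }
  }
  cnt <- data.frame(participant_id = p$participant_id,
                    timestamp = midnight + cnt_min * 60,
                    counts = counts, stringsAsFactors = FALSE)

  ## inject non-wear (zero-count run >= 60 min)
  nonwear <- NULL
  if (runif(1) < b$nonwear_prob) {
    dur <- grid_up(runif(1, b$nonwear_min_range[1], b$nonwear_min_range[2]))
    start <- grid_up(runif(1, wake + 30, sleep - dur - 30))
    sel <- cnt_min >= start & cnt_min < start + dur
    cnt$counts[sel] <- 0L
    nonwear <- c(start, start + dur)
  }

  ## inject GPS dropout (deleted fixes)
  dropout <- NULL
  if (runif(1) < b$dropout_prob) {
    dur <- grid_up(runif(1, b$dropout_min_range[1], b$dropout_min_range[2]))
    start <- grid_up(runif(1, wake + 15, sleep - dur - 15))
    gps <- gps[!(fix_min >= start & fix_min < start + dur), , drop = FALSE]
    dropout <- c(start, start + dur)
  }

  ## annotations for POS dwells
  pos_rows <- which(!is.na(sched$pos_category))
  ann <- lapply(pos_rows, function(i) {
    comp <- COMPANY_LEVELS[runif(5) < b$company_probs[COMPANY_LEVELS]]
    if (!length(comp)) comp <- "alone"
    data.frame(participant_id = p$participant_id,
               start = midnight + sched$start_min[i] * 60,
               end = midnight + sched$end_min[i] * 60,
               pos_category = sched$pos_category[i],
               company = join_multi(comp),
               reasons = sample(names(b$reason_probs), 1,
                                prob = b$reason_probs),
               activities = join_multi(sample(names(b$activity_probs),
                                              sample(1:2, 1),
                                              prob = b$activity_probs)),
               stringsAsFactors = FALSE)
  })
  annotations <- if (length(ann)) do.call(rbind, ann) else NULL

  truth_segments <- data.frame(participant_id = p$participant_id,
                               date = ts_date(midnight),
                               domain = sched$domain, mode = sched$mode,
                               pos_category = sched$pos_category,
                               start = midnight + sched$start_min * 60,
                               end = midnight + sched$end_min * 60,
                               stringsAsFactors = FALSE)

  ## ground-truth POS minutes: dwells plus trips adjacent to a POS dwell,
  ## each trip counted once
  truth_day <- truth_day_row(sched, cnt, p, midnight, nonwear)
  if (!is.null(nonwear)) {
    truth_day$nonwear_start <- nonwear[1]; truth_day$nonwear_end <- nonwear[2]
  } else {
    truth_day$nonwear_start <- NA_real_; truth_day$nonwear_end <- NA_real_
  }
  if (!is.null(dropout)) {
    truth_day$dropout_start <- dropout[1]; truth_day$dropout_end <- dropout[2]
  } else {
    truth_day$dropout_start <- NA_real_; truth_day$dropout_end <- NA_real_
  }
  list(gps = gps, counts = cnt, annotations = annotations,
       truth_segments = truth_segments, truth_day = truth_day)
}

truth_day_row <- function(sched, cnt, p, midnight, nonwear) {
  pos_idx <- which(sched$domain == "leisure" & !is.na(sched$pos_category))
  attributed <- logical(nrow(sched))
  attributed[pos_idx] <- TRUE
  for (i in pos_idx) {
    if (i > 1 && sched$domain[i - 1] == "transport") attributed[i - 1] <- TRUE
    if (i < nrow(sched) && sched$domain[i + 1] == "transport") {
      attributed[i + 1] <- TRUE
    }
  }
  cnt_min <- ts_tod_min(cnt$timestamp)
  blk <- findInterval(cnt_min + 1e-9, sched$start_min)
  in_pos <- attributed[blk]
  worn <- rep(TRUE, nrow(cnt))
  if (!is.null(nonwear)) {
    worn <- !(cnt_min >= nonwear[1] & cnt_min < nonwear[2])
  }
  cls <- classify_intensity(cnt$counts)
  pos_epochs <- in_pos & worn
  data.frame(participant_id = p$participant_id, date = ts_date(midnight),
             n_visits = length(pos_idx),
             pos_min = sum(sched$end_min[attributed] -
                             sched$start_min[attributed]),
             pos_worn_min = sum(pos_epochs) * 0.25,
             pos_st_min = sum(pos_epochs & cls == "sedentary") * 0.25,
             pos_lpa_min = sum(pos_epochs & cls == "light") * 0.25,
             pos_mvpa_min = sum(pos_epochs & (cls == "moderate" |
                                                cls == "vigorous")) * 0.25,
             pos_vpa_min = sum(pos_epochs & cls == "vigorous") * 0.25,
             categories = join_multi(sched$pos_category[pos_idx]),
             stringsAsFactors = FALSE)
}

#' Simulate a full dataset
#'
#' Runs \code{\link{generate_cohort}} and \code{\link{generate_day}} for
#' every participant and study date. Per-participant-day seeds derive from
#' the master seed by counter-based splitting, so any subset regenerates
#' identically.
#'
#' @param config \code{\link{sim_config}}
#' @return list of class \code{pos_simulation}: cohort, schools,
#'   timetables, pos_sites, gps, counts, annotations, weather, truth
#'   (segments, days, school_effects, config)
#' @export
simulate_dataset <- function(config) {
  ctx <- generate_cohort(config)
  dates <- study_dates(config)
  gps <- list(); cnt <- list(); ann <- list(); tseg <- list(); tday <- list()
  for (i in seq_len(nrow(ctx$cohort))) {
    p <- ctx$cohort[i, ]
    for (j in seq_along(dates)) {
      day <- generate_day(p, dates[j], ctx, config,
                          seed = derive_seed(config$seed, i * 64 + j))
      gps[[length(gps) + 1]] <- day$gps
      cnt[[length(cnt) + 1]] <- day$counts
      if (!is.null(day$annotations)) ann[[length(ann) + 1]] <- day$annotations
      tseg[[length(tseg) + 1]] <- day$truth_segments
      tday[[length(tday) + 1]] <- day$truth_day
    }
  }
  set.seed(derive_seed(config$seed, 1))
  weather <- data.frame(date = dates,
                        rain_mm = round(rexp(length(dates), 1 / 0.4), 2),
                        sun_min = round(pmax(0, rnorm(length(dates), 246, 60))),
                        temp_c = round(rnorm(length(dates), 15.1, 3), 1),
                        stringsAsFactors = FALSE)
  out <- list(cohort = ctx$cohort, schools = ctx$schools,
              timetables = ctx$timetables, pos_sites = ctx$pos_sites,
              gps = do.call(rbind, gps), counts = do.call(rbind, cnt),
              annotations = if (length(ann)) do.call(rbind, ann) else
                empty_annotations(),
              weather = weather,
              truth = list(segments = do.call(rbind, tseg),
                           days = do.call(rbind, tday),
                           school_effects = ctx$school_effects,
                           config = config))
  class(out) <- "pos_simulation"
  out
}

empty_annotations <- function() {
  data.frame(participant_id = character(0),
             start = as.POSIXct(character(0), tz = "UTC"),
             end = as.POSIXct(character(0), tz = "UTC"),
             pos_category = character(0), company = character(0),
             reasons = character(0), activities = character(0),
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Emits the six pipeline inputs in their canonical CSV dialects plus two
#' ground-truth files (\code{ground_truth_segments.csv},
#' \code{ground_truth_days.csv}) that \code{\link{read_dataset}} never
#' loads.
#'
#' @param sim \code{pos_simulation} from \code{\link{simulate_dataset}}
#' @param dir output directory (created if absent)
#' @return dir, invisibly
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_ts_csv(sim$gps, p("gps.csv"))
  write_ts_csv(sim$counts, p("counts.csv"))
  write_ts_csv(sim$cohort, p("cohort.csv"))
  write_ts_csv(sim$schools, p("schools.csv"))
  tt <- sim$timetables[c("school_id", "class_id", "weekday", "kind", "start",
                         "end")]
  write_ts_csv(tt, p("timetables.csv"))
  write_ts_csv(sim$annotations, p("annotations.csv"))
  write_ts_csv(sim$weather, p("weather.csv"))
  write_ts_csv(sim$truth$segments, p("ground_truth_segments.csv"))
  write_ts_csv(sim$truth$days, p("ground_truth_days.csv"))
  invisible(dir)
}
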