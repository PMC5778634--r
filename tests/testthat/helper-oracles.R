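## Shared fixtures and independent oracles used across the suite.

ts0 <- function(h = 9, m = 0, s = 0, date = "2015-09-14") {
  as.POSIXct(sprintf("%s %02d:%02d:%02d", date, h, m, s), tz = "UTC")
}

## build a count stream (15 s epochs) from a vector of counts
make_counts <- function(counts, start = ts0(), pid = "P1") {
  data.frame(participant_id = pid,
             timestamp = start + seq_along(counts) * 15 - 15,
             counts = as.integer(counts), stringsAsFactors = FALSE)
}

## build a GPS fix stream (30 s epochs) from coordinate vectors
make_gps <- function(lat, lon, elev = NULL, start = ts0(), pid = "P1") {
  data.frame(participant_id = pid,
             timestamp = start + seq_along(lat) * 30 - 30,
             lat = lat, lon = lon,
             elevation_m = if (is.null(elev)) rep(10, length(lat)) else elev,
             stringsAsFactors = FALSE)
}

## naive run-length scan for non-wear: per-epoch flag, O(n) reference
## written independently of detect_nonwear (contiguity in time respected)
oracle_nonwear_flags <- function(timestamps, counts, min_epochs = 240,
                                 epoch_s = 15) {
  n <- length(counts)
  flag <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0 &&
             as.numeric(timestamps[j + 1] - timestamps[j], units = "secs") == epoch_s) {
        j <- j + 1
      }
      if (j - i + 1 >= min_epochs) flag[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  flag
}

## nonwear segments -> per-epoch flags, to compare against the oracle
segments_to_flags <- function(segs, timestamps) {
  flag <- rep(FALSE, length(timestamps))
  nw <- segs[segs$status == "non-wear", , drop = FALSE]
  for (k in seq_len(nrow(nw))) {
    flag <- flag | (timestamps >= nw$start[k] & timestamps < nw$end[k])
  }
  flag
}

## brute-force plausibility filter: evaluates the three thresholds pairwise
## from the last surviving fix, independent of flag_invalid_fixes
oracle_valid_flags <- function(lat, lon, elev, timestamps,
                               max_speed = 130, max_jump = 1000,
                               max_elev = 100) {
  n <- length(lat)
  valid <- rep(TRUE, n)
  last <- 1
  for (i in seq_len(n)[-1]) {
    dt <- as.numeric(timestamps[i] - timestamps[last], units = "secs")
    rad <- pi / 180
    ## independent spherical law-of-cosines distance (same sphere radius)
    d <- 6371000 * acos(pmin(1, sin(lat[last] * rad) * sin(lat[i] * rad) +
                               cos(lat[last] * rad) * cos(lat[i] * rad) *
                               cos((lon[i] - lon[last]) * rad)))
    sp <- d / dt * 3.6
    de <- abs(elev[i] - elev[last])
    if (sp > max_speed || d > max_jump ||
        (!is.na(de) && de > max_elev)) {
      valid[i] <- FALSE
    } else {
      last <- i
    }
  }
  valid
}

## random zero-heavy count stream for oracle-equivalence tests
random_count_stream <- function(n_blocks = 20) {
  blocks <- lapply(seq_len(n_blocks), function(i) {
    len <- sample(1:120, 1)
    if (runif(1) < 0.5) rep(0L, len) else
      as.integer(sample(1:5000, len, replace = TRUE))
  })
  unlist(blocks)
}

## small noise-free simulation config shared by recovery tests
noise_free_config <- function(n = 10, seed = 11, behaviour = list(),
                              n_schools = 3, ...) {
  b <- utils::modifyList(list(nonwear_prob = 0, dropout_prob = 0,
                              gps_jitter_m = 0.5), behaviour)
  sim_config(n_participants = n, n_schools = n_schools, seed = seed,
             behaviour = b, ...)
}

## constructed segment table builder for visit-attribution tests
make_segment <- function(pid, date, kind, label, start_min, dur_min,
                         pos_category = NA_character_,
                         company = NA_character_, st = 0, lpa = 0, mpa = 0,
                         vpa = 0) {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + start_min * 60
  data.frame(participant_id = pid, date = as.Date(date), kind = kind,
             label = label, start = start, end = start + dur_min * 60,
             n_epochs = as.integer(dur_min * 2), duration_min = dur_min,
             st_min = st, lpa_min = lpa, mpa_min = mpa, vpa_min = vpa,
             lat = 51, lon = 3.7, pos_category = pos_category,
             company = company, reasons = NA_character_,
             activities = NA_character_, stringsAsFactors = FALSE)
}
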