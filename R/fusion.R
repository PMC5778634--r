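## Spatial fusion: merge the 30 s GPS stream with the 15 s count stream,
## flag implausible fixes (speed / jump / elevation thresholds), derive
## speeds and classify each fused epoch as stationary or a transport mode.

#' Great-circle (haversine) distance
#'
#' Spherical-earth distance with radius 6,371,000 m. Vectorised over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84)
#' @return distance in metres
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90, abs(lat2) > 90, na.rm = TRUE) ||
      any(abs(lon1) > 180, abs(lon2) > 180, na.rm = TRUE)) {
    stop_input("haversine_distance: coordinate out of range")
  }
  r <- 6371000
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Speed between two fixes
#'
#' @param lat1,lon1 previous (valid) fix
#' @param lat2,lon2 current fix
#' @param gap_s elapsed seconds between the fixes (may exceed the 30 s grid
#'   after dropout; the actual gap is used)
#' @return speed in km/h
#' @export
compute_speed <- function(lat1, lon1, lat2, lon2, gap_s) {
  if (any(gap_s <= 0)) stop_input("compute_speed: non-positive time gap")
  haversine_distance(lat1, lon1, lat2, lon2) / gap_s * 3.6
}

#' Align GPS fixes with count epochs onto a 30 s grid
#'
#' Each GPS fix anchors one fused epoch; the two 15 s count epochs with
#' timestamps in [fix, fix + 30 s) attach to it (device clocks may drift, so
#' a count epoch within \code{tol_s} of its nominal slot still matches).
#' Count epochs with no fix in tolerance become location-missing fused
#' epochs: they are kept so wear and intensity totals are unaffected by GPS
#' dropout, but never contribute to spatial domains. Location-missing
#' epochs are grouped in pairs on the 30 s grid implied by the count
#' stream.
#'
#' @param gps GPS fix table (\code{\link{read_gps_log}})
#' @param counts count table with \code{worn} flag (\code{\link{flag_wear}})
#' @param tol_s clock-drift tolerance in seconds (default 5)
#' @return fused epoch table: participant_id, timestamp, lat, lon,
#'   elevation_m, located, counts1, counts2, n_counts, counts_30s,
#'   intensity1, intensity2, worn1, worn2
#' @export
align_streams <- function(gps, counts, tol_s = 5) {
  if (!"worn" %in% names(counts)) counts <- flag_wear(counts)
  counts$intensity <- classify_intensity(counts$counts)
  ## snap count timestamps to the 15 s grid when within tolerance
  secs <- as.numeric(counts$timestamp)
  snap <- round(secs / 15) * 15
  secs <- ifelse(abs(secs - snap) <= tol_s, snap, secs)
  ckey <- paste(counts$participant_id, secs)

  fsec <- round(as.numeric(gps$timestamp) / 15) * 15
  i1 <- match(paste(gps$participant_id, fsec), ckey)
  i2 <- match(paste(gps$participant_id, fsec + 15), ckey)

  fused <- data.frame(participant_id = gps$participant_id,
                      timestamp = gps$timestamp,
                      lat = gps$lat, lon = gps$lon,
                      elevation_m = gps$elevation_m,
                      located = TRUE, stringsAsFactors = FALSE)
  fused$counts1 <- counts$counts[i1]
  fused$counts2 <- counts$counts[i2]
  fused$intensity1 <- counts$intensity[i1]
  fused$intensity2 <- counts$intensity[i2]
  fused$worn1 <- counts$worn[i1]
  fused$worn2 <- counts$worn[i2]

  ## counts not claimed by any fix -> location-missing epochs on the count grid
  claimed <- unique(c(i1, i2))
  claimed <- claimed[!is.na(claimed)]
  orphan <- setdiff(seq_len(nrow(counts)), claimed)
  if (length(orphan)) {
    osec <- floor(secs[orphan] / 30) * 30
    key <- paste(counts$participant_id[orphan], osec)
    first <- !duplicated(key)
    slot <- match(key, key[first])
    is_second <- (secs[orphan] - osec) >= 15
    m <- data.frame(participant_id = counts$participant_id[orphan][first],
                    timestamp = as.POSIXct(osec[first], origin = "1970-01-01",
                                           tz = "UTC"),
                    lat = NA_real_, lon = NA_real_, elevation_m = NA_real_,
                    located = FALSE, stringsAsFactors = FALSE)
    m$counts1 <- NA_integer_; m$counts2 <- NA_integer_
    m$intensity1 <- factor(NA, levels = INTENSITY_LEVELS)
    m$intensity2 <- factor(NA, levels = INTENSITY_LEVELS)
    m$worn1 <- NA; m$worn2 <- NA
    for (j in seq_along(orphan)) {
      s <- slot[j]; oi <- orphan[j]
      if (!is_second[j]) {
        m$counts1[s] <- counts$counts[oi]; m$intensity1[s] <- counts$intensity[oi]
        m$worn1[s] <- counts$worn[oi]
      } else {
        m$counts2[s] <- counts$counts[oi]; m$intensity2[s] <- counts$intensity[oi]
        m$worn2[s] <- counts$worn[oi]
      }
    }
    fused <- rbind(fused, m)
  }
  fused$n_counts <- (!is.na(fused$counts1)) + (!is.na(fused$counts2))
  fused$counts_30s <- ifelse(fused$n_counts == 0, NA_real_,
                             ifelse(is.na(fused$counts1), 0, fused$counts1) +
                             ifelse(is.na(fused$counts2), 0, fused$counts2))
  if (any(fused$n_counts == 0 & fused$located)) {
    ## fixes with no counts in tolerance: kept, they may still carry location
    fused$worn1[fused$n_counts == 0] <- NA
  }
  fused <- fused[order(fused$participant_id, fused$timestamp), , drop = FALSE]
  rownames(fused) <- NULL
  fused
}

#' Flag implausible GPS fixes
#'
#' Between two located epochs the later fix is invalid when the implied
#' speed exceeds \code{max_speed_kmh}, the jump exceeds \code{max_jump_m},
#' or the elevation change exceeds \code{max_elev_m} (the elevation test is
#' skipped when either elevation is missing). Invalid fixes become
#' location-missing and the speed chain restarts from the last valid fix.
#' Wear status and intensity are untouched: spatial validity and
#' accelerometry are independent.
#'
#' @param fused fused epoch table (\code{\link{align_streams}})
#' @param max_speed_kmh speed threshold (default 130)
#' @param max_jump_m distance threshold between consecutive points (default
#'   1000)
#' @param max_elev_m elevation-change threshold (default 100)
#' @return fused table with logical \code{valid_fix} and numeric
#'   \code{speed_kmh} (km/h from the last valid fix; NA for the first fix
#'   of a chain and for location-missing epochs)
#' @export
flag_invalid_fixes <- function(fused, max_speed_kmh = 130, max_jump_m = 1000,
                               max_elev_m = 100) {
  n <- nrow(fused)
  valid <- fused$located & !is.na(fused$lat)
  speed <- rep(NA_real_, n)
  ## plain vectors: the sequential chain below runs per row
  secs <- as.numeric(fused$timestamp)
  lat <- fused$lat; lon <- fused$lon; elev <- fused$elevation_m
  key <- paste(fused$participant_id, ts_date(fused$timestamp))
  to_rad <- pi / 180
  for (k in unique(key)) {
    idx <- which(key == k & fused$located)
    if (length(idx) < 1) next
    prev <- NA_integer_
    for (i in idx) {
      if (is.na(prev)) { prev <- i; next }
      gap <- secs[i] - secs[prev]
      dlat <- (lat[i] - lat[prev]) * to_rad / 2
      dlon <- (lon[i] - lon[prev]) * to_rad / 2
      a <- sin(dlat)^2 + cos(lat[prev] * to_rad) * cos(lat[i] * to_rad) *
        sin(dlon)^2
      d <- 2 * 6371000 * asin(min(1, sqrt(a)))
      sp <- d / gap * 3.6
      delev <- abs(elev[i] - elev[prev])
      bad <- sp > max_speed_kmh || d > max_jump_m ||
        (!is.na(delev) && delev > max_elev_m)
      if (bad) {
        valid[i] <- FALSE
      } else {
        speed[i] <- sp
        prev <- i
      }
    }
  }
  fused$valid_fix <- valid
  fused$speed_kmh <- speed
  fused$located <- fused$located & valid
  fused
}

#' Classify movement state from speed
#'
#' Speed bands partition [0, Inf): stationary < 1 km/h, pedestrian
#' [1, 10), bicycle [10, 25), motorized >= 25. Epochs with undefined speed
#' (first fix of a bout, after dropout) default to stationary.
#'
#' @param speed_kmh numeric vector (NA allowed)
#' @param bands numeric c(pedestrian, bicycle, motorized) lower bounds,
#'   default c(1, 10, 25)
#' @return factor with levels stationary, pedestrian, bicycle, motorized
#' @export
classify_movement <- function(speed_kmh, bands = c(1, 10, 25)) {
  mv <- ifelse(is.na(speed_kmh) | speed_kmh < bands[1], "stationary",
        ifelse(speed_kmh < bands[2], "pedestrian",
        ifelse(speed_kmh < bands[3], "bicycle", "motorized")))
  factor(mv, levels = MOVEMENT_LEVELS)
}

#' Absorb single-epoch movement flicker
#'
#' Runs of identical movement states of length at most \code{smooth_epochs}
#' flanked on both sides by one identical state are absorbed into the
#' flanking state, so one-epoch flicker does not fragment trips.
#'
#' @param movement factor/character vector of movement states in time order
#' @param smooth_epochs maximal run length to absorb (default 1; 0 disables)
#' @return smoothed vector of the same type
#' @export
smooth_movement <- function(movement, smooth_epochs = 1) {
  if (smooth_epochs < 1 || length(movement) < 3) return(movement)
  x <- as.character(movement)
  repeat {
    r <- rle(x)
    n <- length(r$lengths)
    if (n < 3) break
    mid <- 2:(n - 1)
    absorb <- mid[r$lengths[mid] <= smooth_epochs &
                  r$values[mid - 1] == r$values[mid + 1] &
                  r$values[mid] != r$values[mid - 1]]
    if (!length(absorb)) break
    r$values[absorb] <- r$values[absorb - 1]
    x <- inverse.rle(r)
  }
  if (is.factor(movement)) factor(x, levels = levels(movement)) else x
}

#' Attach movement states to a fused epoch table
#'
#' Computes \code{movement} from \code{speed_kmh} via
#' \code{\link{classify_movement}} then applies run-length smoothing per
#' participant-day.
#'
#' @param fused fused table from \code{\link{flag_invalid_fixes}}
#' @param bands speed band lower bounds, km/h
#' @param smooth_epochs see \code{\link{smooth_movement}}
#' @return fused table with \code{movement} column (NA when not located)
#' @export
add_movement <- function(fused, bands = c(1, 10, 25), smooth_epochs = 1) {
  fused$movement <- factor(NA, levels = MOVEMENT_LEVELS)
  key <- paste(fused$participant_id, ts_date(fused$timestamp))
  loc <- fused$located
  for (k in unique(key)) {
    i <- which(key == k & loc)
    if (!length(i)) next
    mv <- classify_movement(fused$speed_kmh[i], bands = bands)
    fused$movement[i] <- smooth_movement(mv, smooth_epochs = smooth_epochs)
  }
  fused
}

#' Apply interview-based corrections to fused epochs
#'
#' Overwrites the movement state inside declared participant/time windows
#' (the interview stage catches misclassified trips, e.g. a congested bus
#' ride classified as bicycle from its low speed). Later rows win on
#' overlap, with a warning; windows matching no epoch warn and are skipped.
#'
#' @param fused fused table with \code{movement}
#' @param corrections data.frame participant_id, start, end, movement
#' @return corrected fused table; attribute \code{corrections_applied}
#'   records epochs changed per row
#' @export
apply_corrections <- function(fused, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0) return(fused)
  check_columns(corrections, c("participant_id", "start", "end", "movement"),
                "correction table")
  check_levels(corrections$movement, MOVEMENT_LEVELS, "movement",
               "correction table")
  if (is.character(corrections$start)) corrections$start <- parse_ts(corrections$start)
  if (is.character(corrections$end)) corrections$end <- parse_ts(corrections$end)
  touched <- rep(FALSE, nrow(fused))
  applied <- integer(nrow(corrections))
  for (j in seq_len(nrow(corrections))) {
    sel <- fused$participant_id == corrections$participant_id[j] &
      fused$timestamp >= corrections$start[j] &
      fused$timestamp < corrections$end[j] & fused$located
    if (!any(sel)) {
      warning(sprintf("correction %d matches no epochs (%s %s-%s)", j,
                      corrections$participant_id[j],
                      format_ts(corrections$start[j]),
                      format_ts(corrections$end[j])), call. = FALSE)
      next
    }
    if (any(touched & sel)) {
      warning(sprintf("correction %d overlaps an earlier correction; later row wins", j),
              call. = FALSE)
    }
    fused$movement[sel] <- corrections$movement[j]
    touched <- touched | sel
    applied[j] <- sum(sel)
  }
  attr(fused, "corrections_applied") <- applied
  fused
}
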