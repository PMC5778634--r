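## Accelerometer processing: intensity classification (Evenson cutpoints at
## 15 s epochs), non-wear detection (60 min of consecutive zeros), wear time
## and the valid-day / included-participant filter.

#' Evenson cutpoints for 15 s epochs
#'
#' Named numeric vector of class boundaries on vertical-axis counts per
#' 15 s: sedentary <= 100; light 101--2295; moderate 2296--4011;
#' vigorous >= 4012.
#' @export
evenson_cutpoints <- function() {
  c(sedentary_max = 100, moderate_min = 2296, vigorous_min = 4012)
}

#' Classify count epochs into intensity classes
#'
#' Maps non-negative counts per 15 s epoch onto the four Evenson intensity
#' classes. The four half-open intervals partition \code{[0, Inf)}, so the
#' mapping is total: sedentary iff counts <= 100, light iff
#' 100 < counts < 2296, moderate iff 2296 <= counts < 4012, vigorous iff
#' counts >= 4012.
#'
#' @param counts numeric vector of non-negative counts per 15 s epoch
#' @param cutpoints boundary table as from \code{\link{evenson_cutpoints}};
#'   a pluggable threshold family may be substituted
#' @return factor with levels sedentary, light, moderate, vigorous
#' @export
classify_intensity <- function(counts, cutpoints = evenson_cutpoints()) {
  if (any(counts < 0, na.rm = TRUE)) stop_input("counts must be non-negative")
  cls <- ifelse(counts <= cutpoints[["sedentary_max"]], "sedentary",
         ifelse(counts < cutpoints[["moderate_min"]], "light",
         ifelse(counts < cutpoints[["vigorous_min"]], "moderate", "vigorous")))
  factor(cls, levels = INTENSITY_LEVELS)
}

#' Detect non-wear periods in a count stream
#'
#' Every maximal run of consecutive zero-count epochs lasting at least
#' \code{nonwear_min} minutes (240 epochs at the default 60 min / 15 s)
#' becomes a non-wear segment; all other recorded epochs are worn. A run is
#' broken by any non-zero epoch and by any spacing irregularity (missing
#' epochs end the run: zeros are only "continuous" when contiguous in
#' time). Runs truncated by the recording edge still count when long
#' enough.
#'
#' @param timestamps sorted POSIXct epoch timestamps for one participant-day
#' @param counts matching non-negative counts
#' @param nonwear_min minimum zero-run duration in minutes (default 60)
#' @param epoch_s epoch length in seconds (default 15)
#' @return data.frame of segments: start, end (end = last epoch start +
#'   epoch_s), status ("worn"/"non-wear"), n_epochs, duration_min
#' @export
detect_nonwear <- function(timestamps, counts, nonwear_min = 60, epoch_s = 15) {
  n <- length(timestamps)
  stopifnot(length(counts) == n)
  if (n == 0) {
    return(data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      status = character(0), n_epochs = integer(0),
                      duration_min = numeric(0)))
  }
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop_input("detect_nonwear: epoch stream must be strictly sorted")
  }
  if (any(counts < 0)) stop_input("detect_nonwear: negative counts")
  ## break runs at spacing irregularities as well as zero/non-zero changes
  contig <- c(TRUE, as.numeric(diff(timestamps), units = "secs") == epoch_s)
  zero <- counts == 0
  block <- cumsum(!contig | c(TRUE, zero[-1] != zero[-n]))
  min_epochs <- ceiling(nonwear_min * 60 / epoch_s)
  idx <- split(seq_len(n), block)
  segs <- lapply(idx, function(i) {
    is_nw <- zero[i[1]] && length(i) >= min_epochs
    data.frame(start = timestamps[i[1]],
               end = timestamps[i[length(i)]] + epoch_s,
               status = if (is_nw) "non-wear" else "worn",
               n_epochs = length(i),
               duration_min = length(i) * epoch_s / 60)
  })
  out <- do.call(rbind, segs)
  ## merge adjacent worn blocks (zero/non-zero flips below threshold)
  out <- merge_adjacent_segments(out)
  rownames(out) <- NULL
  out
}

merge_adjacent_segments <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  keep <- list(segs[1, ])
  for (i in 2:nrow(segs)) {
    last <- keep[[length(keep)]]
    s <- segs[i, ]
    if (s$status == last$status && s$start == last$end) {
      last$end <- s$end
      last$n_epochs <- last$n_epochs + s$n_epochs
      last$duration_min <- last$duration_min + s$duration_min
      keep[[length(keep)]] <- last
    } else {
      keep[[length(keep) + 1]] <- s
    }
  }
  do.call(rbind, keep)
}

#' Flag wear status on an epoch table
#'
#' Applies \code{\link{detect_nonwear}} per participant-day and returns the
#' epoch table with logical \code{worn} column.
#'
#' @param counts_df count log as from \code{\link{read_count_log}}
#' @inheritParams detect_nonwear
#' @return input data.frame plus \code{worn}
#' @export
flag_wear <- function(counts_df, nonwear_min = 60, epoch_s = 15) {
  counts_df$date <- ts_date(counts_df$timestamp)
  key <- paste(counts_df$participant_id, counts_df$date)
  worn <- rep(TRUE, nrow(counts_df))
  for (k in unique(key)) {
    i <- which(key == k)
    segs <- detect_nonwear(counts_df$timestamp[i], counts_df$counts[i],
                           nonwear_min = nonwear_min, epoch_s = epoch_s)
    nw <- segs[segs$status == "non-wear", , drop = FALSE]
    if (nrow(nw)) {
      ts <- counts_df$timestamp[i]
      off <- rep(FALSE, length(i))
      for (j in seq_len(nrow(nw))) off <- off | (ts >= nw$start[j] & ts < nw$end[j])
      worn[i] <- !off
    }
  }
  counts_df$worn <- worn
  counts_df
}

#' Wear time per participant-day
#'
#' @param segments data.frame of wear segments (as from
#'   \code{\link{detect_nonwear}}) or an epoch table with a \code{worn}
#'   column
#' @param epoch_s epoch length in seconds when an epoch table is given
#' @return worn minutes (quarter-minute resolution at 15 s epochs)
#' @export
compute_wear_time <- function(segments, epoch_s = 15) {
  if ("worn" %in% names(segments)) {
    return(sum(segments$worn) * epoch_s / 60)
  }
  sum(segments$duration_min[segments$status == "worn"])
}

#' Valid-day and included-participant selection
#'
#' A day is valid iff its worn time reaches \code{valid_day_min} minutes
#' (default 540 = 9 h); a participant is included iff they have at least
#' one valid day. Invalid days are dropped from all downstream aggregation.
#'
#' @param wear_by_day data.frame with participant_id, date, wear_min
#' @param valid_day_min minimum worn minutes for a valid day
#' @return \code{wear_by_day} plus logical \code{valid}; attribute
#'   \code{included} holds the included participant ids
#' @export
select_valid <- function(wear_by_day, valid_day_min = 540) {
  check_columns(wear_by_day, c("participant_id", "date", "wear_min"),
                "wear-by-day table")
  wear_by_day$valid <- wear_by_day$wear_min >= valid_day_min
  inc <- unique(wear_by_day$participant_id[wear_by_day$valid])
  attr(wear_by_day, "included") <- inc
  wear_by_day
}

#' Per-day wear summary of an epoch table
#' @param epochs epoch table with participant_id, timestamp, worn
#' @param epoch_s epoch length in seconds
#' @return data.frame participant_id, date, wear_min
#' @export
wear_by_day <- function(epochs, epoch_s = 15) {
  epochs$date <- ts_date(epochs$timestamp)
  agg <- aggregate(worn ~ participant_id + date, data = epochs, FUN = sum)
  names(agg)[names(agg) == "worn"] <- "wear_min"
  agg$wear_min <- agg$wear_min * epoch_s / 60
  agg[order(agg$participant_id, agg$date), , drop = FALSE]
}
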