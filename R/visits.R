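## POS-visit extraction and trip attribution: a POS-categorized leisure
## event plus the trips immediately to and from it. Only leisure-domain POS
## time counts: a trip between home and school is never POS exposure, no
## matter what territory it crosses.

#' Extract POS visits from a day's segments
#'
#' Every leisure event carrying one of the nine POS categories becomes a
#' visit. The trip whose end lies within \code{adjacency_s} of the event
#' start is attributed as the inbound trip; the trip starting within
#' \code{adjacency_s} of the event end as the outbound trip (consolidation
#' may insert location-missing gaps, so strict abutment is not required).
#' A trip bridging two POS events is attributed exactly once, as the
#' outbound trip of the earlier visit. Trips adjacent only to non-POS
#' segments (home, school, unannotated leisure) are never attributed.
#'
#' @param segments annotated segment table for the cohort
#'   (\code{\link{join_annotations}})
#' @param adjacency_s adjacency tolerance in seconds (default 30, one fused
#'   epoch)
#' @return visit table: participant_id, date, pos_category, company,
#'   reasons, activities, event/inbound/outbound start-end and minutes,
#'   total_min, st_min, lpa_min, mpa_min, vpa_min, mvpa_min
#' @export
extract_pos_visits <- function(segments, adjacency_s = 30) {
  out <- list()
  key <- paste(segments$participant_id, segments$date)
  for (k in unique(key)) {
    day <- segments[key == k, , drop = FALSE]
    day <- day[order(day$start), , drop = FALSE]
    ev <- which(day$kind == "event" & day$label == "leisure" &
                !is.na(day$pos_category))
    if (!length(ev)) next
    used_trip <- rep(FALSE, nrow(day))
    for (e in ev) {
      inbound <- NA_integer_; outbound <- NA_integer_
      if (e > 1) {
        p <- e - 1
        if (day$kind[p] == "trip" && !used_trip[p] &&
            abs(as.numeric(day$start[e] - day$end[p], units = "secs")) <= adjacency_s) {
          inbound <- p
        }
      }
      if (e < nrow(day)) {
        s <- e + 1
        if (day$kind[s] == "trip" &&
            abs(as.numeric(day$start[s] - day$end[e], units = "secs")) <= adjacency_s) {
          outbound <- s
        }
      }
      segs <- c(e, inbound, outbound)
      segs <- segs[!is.na(segs)]
      used_trip[segs[day$kind[segs] == "trip"]] <- TRUE
      v <- data.frame(participant_id = day$participant_id[e],
                      date = day$date[e],
                      pos_category = day$pos_category[e],
                      company = day$company[e],
                      reasons = day$reasons[e],
                      activities = day$activities[e],
                      event_start = day$start[e], event_end = day$end[e],
                      event_min = day$duration_min[e],
                      inbound_min = if (is.na(inbound)) 0 else day$duration_min[inbound],
                      inbound_mode = if (is.na(inbound)) NA_character_ else day$label[inbound],
                      outbound_min = if (is.na(outbound)) 0 else day$duration_min[outbound],
                      outbound_mode = if (is.na(outbound)) NA_character_ else day$label[outbound],
                      stringsAsFactors = FALSE)
      v$total_min <- sum(day$duration_min[segs])
      v$st_min <- sum(day$st_min[segs])
      v$lpa_min <- sum(day$lpa_min[segs])
      v$mpa_min <- sum(day$mpa_min[segs])
      v$vpa_min <- sum(day$vpa_min[segs])
      v$mvpa_min <- v$mpa_min + v$vpa_min
      out[[length(out) + 1]] <- v
    }
  }
  if (!length(out)) return(empty_visits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_visits <- function() {
  data.frame(participant_id = character(0), date = as.Date(character(0)),
             pos_category = character(0), company = character(0),
             reasons = character(0), activities = character(0),
             event_start = as.POSIXct(character(0), tz = "UTC"),
             event_end = as.POSIXct(character(0), tz = "UTC"),
             event_min = numeric(0), inbound_min = numeric(0),
             inbound_mode = character(0), outbound_min = numeric(0),
             outbound_mode = character(0), total_min = numeric(0),
             st_min = numeric(0), lpa_min = numeric(0), mpa_min = numeric(0),
             vpa_min = numeric(0), mvpa_min = numeric(0),
             stringsAsFactors = FALSE)
}
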