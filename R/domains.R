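## Domain segmentation: label every located worn epoch home / school
## (PE, class, recess) / leisure / transport, consolidate runs into events
## and trips, and join interview annotations onto leisure events.

#' Assign a domain to every located epoch
#'
#' Transport epochs keep their mode. Stationary epochs are school
#' (subclassified PE / recess / class from the class timetable) when within
#' \code{buffer_m} of the school point during school hours on a school day;
#' otherwise home when within \code{buffer_m} of the home point; everything
#' else is leisure. School takes precedence over home when the buffers
#' overlap during school hours (the more specific rule). The buffer test is
#' great-circle and boundary-inclusive (<= 100 m by default).
#'
#' @param fused fused table with \code{movement} (\code{\link{add_movement}})
#' @param cohort cohort table (home coordinates, school/class ids)
#' @param schools school table (coordinates)
#' @param timetables timetable table (\code{\link{read_timetables}})
#' @param buffer_m buffer radius in metres (default 100)
#' @return fused table with \code{domain} column (NA when not located or
#'   not worn)
#' @export
assign_domain <- function(fused, cohort, schools, timetables, buffer_m = 100) {
  ci <- match(fused$participant_id, cohort$participant_id)
  if (anyNA(ci)) {
    stop_input("assign_domain: participant %s missing from cohort table",
               fused$participant_id[which(is.na(ci))[1]])
  }
  home_lat <- cohort$home_lat[ci]; home_lon <- cohort$home_lon[ci]
  if (anyNA(home_lat[fused$located])) {
    stop_input("assign_domain: participant lacking home coordinates")
  }
  si <- match(cohort$school_id[ci], schools$school_id)
  sch_lat <- schools$lat[si]; sch_lon <- schools$lon[si]

  worn <- !is.na(fused$worn1) & fused$worn1 | !is.na(fused$worn2) & fused$worn2
  use <- fused$located & worn
  dom <- rep(NA_character_, nrow(fused))

  d_home <- rep(NA_real_, nrow(fused))
  d_school <- rep(NA_real_, nrow(fused))
  d_home[use] <- haversine_distance(fused$lat[use], fused$lon[use],
                                    home_lat[use], home_lon[use])
  d_school[use] <- haversine_distance(fused$lat[use], fused$lon[use],
                                      sch_lat[use], sch_lon[use])

  tod <- ts_tod_min(fused$timestamp)
  wd <- ts_weekday(ts_date(fused$timestamp))
  class_id <- cohort$class_id[ci]
  block <- timetable_block(timetables, class_id, wd, tod)

  moving <- use & !is.na(fused$movement) & fused$movement != "stationary"
  dom[moving] <- "transport"

  stat <- use & !moving
  in_school_hours <- block$in_school & stat & d_school <= buffer_m
  dom[in_school_hours & block$block == "pe"] <- "school_pe"
  dom[in_school_hours & block$block == "recess"] <- "school_recess"
  dom[in_school_hours & block$block == "class"] <- "school_class"
  rest <- stat & is.na(dom)
  dom[rest & d_home <= buffer_m] <- "home"
  dom[rest & d_home > buffer_m] <- "leisure"

  fused$domain <- factor(dom, levels = DOMAIN_LEVELS)
  fused
}

## vectorised timetable lookup: for each epoch, is it inside school hours of
## its class on that weekday, and inside which sub-block (pe/recess/class)
timetable_block <- function(tt, class_id, weekday, tod_min) {
  n <- length(class_id)
  in_school <- rep(FALSE, n)
  block <- rep(NA_character_, n)
  key <- paste(class_id, weekday)
  ttkey <- paste(tt$class_id, tt$weekday)
  for (k in unique(key)) {
    rows <- tt[ttkey == k, , drop = FALSE]
    i <- which(key == k)
    if (!nrow(rows)) next
    sch <- rows[rows$kind == "school", , drop = FALSE]
    if (!nrow(sch)) next
    ins <- rep(FALSE, length(i))
    for (j in seq_len(nrow(sch))) {
      ins <- ins | (tod_min[i] >= sch$start_min[j] & tod_min[i] < sch$end_min[j])
    }
    in_school[i] <- ins
    blk <- ifelse(ins, "class", NA_character_)
    for (kind in c("pe", "recess")) {
      sub <- rows[rows$kind == kind, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        hit <- tod_min[i] >= sub$start_min[j] & tod_min[i] < sub$end_min[j]
        blk[hit & ins] <- kind
      }
    }
    block[i] <- blk
  }
  list(in_school = in_school, block = block)
}

#' Consolidate labelled epochs into events and trips
#'
#' Maximal runs of epochs sharing a label become one segment: events carry
#' a domain, trips a transport mode (a pedestrian run followed by a bicycle
#' run is two trips). Location-missing epochs and time gaps break runs.
#' Intensity minutes are accumulated from the constituent 15 s classes
#' (0.25 min each); the representative location is the member median.
#'
#' @param fused fused table with \code{domain} and \code{movement}
#' @param epoch_s fused epoch length in seconds (default 30)
#' @return segment table: participant_id, date, kind ("event"/"trip"),
#'   label (domain or mode), start, end, n_epochs, duration_min, st_min,
#'   lpa_min, mpa_min, vpa_min, lat, lon, pos_category (NA)
#' @export
consolidate <- function(fused, epoch_s = 30) {
  lab <- as.character(fused$domain)
  lab[!is.na(lab) & lab == "transport"] <- paste0("trip:", as.character(fused$movement)[!is.na(lab) & lab == "transport"])
  ok <- !is.na(lab)
  f <- fused[ok, , drop = FALSE]
  lab <- lab[ok]
  if (!nrow(f)) return(empty_segments())
  ord <- order(f$participant_id, f$timestamp)
  f <- f[ord, , drop = FALSE]; lab <- lab[ord]
  n <- nrow(f)
  newrun <- c(TRUE,
              f$participant_id[-1] != f$participant_id[-n] |
              lab[-1] != lab[-n] |
              as.numeric(diff(f$timestamp), units = "secs") != epoch_s)
  run <- cumsum(newrun)
  int_min <- function(which_class) {
    (as.integer(!is.na(f$intensity1) & f$intensity1 == which_class) +
     as.integer(!is.na(f$intensity2) & f$intensity2 == which_class)) * 0.25
  }
  st <- int_min("sedentary"); lp <- int_min("light")
  mp <- int_min("moderate"); vp <- int_min("vigorous")
  idx <- split(seq_len(n), run)
  segs <- lapply(idx, function(i) {
    l <- lab[i[1]]
    trip <- startsWith(l, "trip:")
    data.frame(participant_id = f$participant_id[i[1]],
               date = ts_date(f$timestamp[i[1]]),
               kind = if (trip) "trip" else "event",
               label = if (trip) sub("^trip:", "", l) else l,
               start = f$timestamp[i[1]],
               end = f$timestamp[i[length(i)]] + epoch_s,
               n_epochs = length(i),
               duration_min = length(i) * epoch_s / 60,
               st_min = sum(st[i]), lpa_min = sum(lp[i]),
               mpa_min = sum(mp[i]), vpa_min = sum(vp[i]),
               lat = median(f$lat[i]), lon = median(f$lon[i]),
               pos_category = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

empty_segments <- function() {
  data.frame(participant_id = character(0), date = as.Date(character(0)),
             kind = character(0), label = character(0),
             start = as.POSIXct(character(0), tz = "UTC"),
             end = as.POSIXct(character(0), tz = "UTC"),
             n_epochs = integer(0), duration_min = numeric(0),
             st_min = numeric(0), lpa_min = numeric(0), mpa_min = numeric(0),
             vpa_min = numeric(0), lat = numeric(0), lon = numeric(0),
             pos_category = character(0), stringsAsFactors = FALSE)
}

#' Join POS annotations onto leisure events
#'
#' Each annotation window is assigned to the leisure event of that
#' participant with maximal temporal overlap (ties go to the earlier
#' event, with a warning). Annotations overlapping nothing warn and are
#' dropped. Unannotated leisure events keep \code{pos_category = NA}
#' ("unknown / non-POS").
#'
#' @param segments segment table (\code{\link{consolidate}})
#' @param annotations annotation table (\code{\link{read_annotations}})
#' @return segments with pos_category, company, reasons, activities filled
#'   on annotated leisure events
#' @export
join_annotations <- function(segments, annotations) {
  segments$company <- NA_character_
  segments$reasons <- NA_character_
  segments$activities <- NA_character_
  if (is.null(annotations) || nrow(annotations) == 0) return(segments)
  leis <- which(segments$kind == "event" & segments$label == "leisure")
  for (j in seq_len(nrow(annotations))) {
    cand <- leis[segments$participant_id[leis] == annotations$participant_id[j]]
    if (!length(cand)) {
      warning(sprintf("annotation %d: no leisure events for participant %s",
                      j, annotations$participant_id[j]), call. = FALSE)
      next
    }
    ov <- pmax(0, as.numeric(pmin(segments$end[cand], annotations$end[j]) -
                             pmax(segments$start[cand], annotations$start[j]),
                             units = "secs"))
    if (max(ov) == 0) {
      warning(sprintf("annotation %d (%s %s): overlaps no leisure event, unused",
                      j, annotations$participant_id[j],
                      format_ts(annotations$start[j])), call. = FALSE)
      next
    }
    best <- cand[ov == max(ov)]
    if (length(best) > 1) {
      warning(sprintf("annotation %d: overlap tie, assigned to earlier event", j),
              call. = FALSE)
      best <- best[which.min(segments$start[best])]
    }
    if (!is.na(segments$pos_category[best])) {
      warning(sprintf("annotation %d: event already annotated, first kept", j),
              call. = FALSE)
      next
    }
    segments$pos_category[best] <- annotations$pos_category[j]
    segments$company[best] <- annotations$company[j]
    segments$reasons[best] <- annotations$reasons[j]
    segments$activities[best] <- annotations$activities[j]
  }
  segments
}
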