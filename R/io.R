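## Readers and writers for every file the pipeline touches.
## One canonical CSV dialect per stream: UTF-8, comma separated, ISO-8601
## local timestamps without zone offset. GPX 1.1 trackpoints are accepted
## as an alternative GPS input.

#' Read a GPS fix log
#'
#' Expects columns \code{participant_id,timestamp,lat,lon,elevation_m}.
#' Fixes are sorted by timestamp within participant; duplicate timestamps
#' for one participant are rejected, as are out-of-range coordinates.
#' Elevation may be missing (empty cell) and is propagated as \code{NA}.
#'
#' @param path path to a CSV file
#' @return data.frame with columns participant_id (character), timestamp
#'   (POSIXct), lat, lon, elevation_m (numeric)
#' @export
read_gps_log <- function(path) {
  if (!file.exists(path)) stop_input("GPS log not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "timestamp", "lat", "lon",
                      "elevation_m"), "gps log")
  ts <- parse_ts(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop_input("gps log: malformed timestamp at data row %d (%s)",
               bad[1], df$timestamp[bad[1]])
  }
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  bad <- which(is.na(lat) | is.na(lon))
  if (length(bad)) stop_input("gps log: malformed coordinate at data row %d", bad[1])
  if (any(lat < -90 | lat > 90)) {
    stop_input("gps log: latitude out of range [-90, 90] at data row %d",
               which(lat < -90 | lat > 90)[1])
  }
  if (any(lon < -180 | lon > 180)) {
    stop_input("gps log: longitude out of range [-180, 180] at data row %d",
               which(lon < -180 | lon > 180)[1])
  }
  elev <- suppressWarnings(as.numeric(df$elevation_m))
  out <- data.frame(participant_id = df$participant_id, timestamp = ts,
                    lat = lat, lon = lon, elevation_m = elev,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[c("participant_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_input("gps log: duplicate timestamp %s for participant %s",
               format_ts(out$timestamp[i]), out$participant_id[i])
  }
  rownames(out) <- NULL
  out
}

#' Read GPS trackpoints from a GPX 1.1 file
#'
#' Parses \code{<trkpt>} elements (lat/lon attributes, optional \code{<ele>}
#' and \code{<time>} children) into the same table \code{\link{read_gps_log}}
#' returns.
#'
#' @param path path to a GPX file
#' @param participant_id id to assign to all trackpoints (GPX carries none)
#' @return data.frame as from \code{read_gps_log}
#' @export
read_gps_gpx <- function(path, participant_id) {
  if (!file.exists(path)) stop_input("GPX file not found: %s", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (!length(pts)) stop_input("GPX file contains no trackpoints: %s", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele_nodes <- lapply(pts, function(p) xml2::xml_find_first(p, "./ele"))
  ele <- vapply(ele_nodes, function(n)
    if (inherits(n, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(n)),
    numeric(1))
  tim <- vapply(pts, function(p)
    xml2::xml_text(xml2::xml_find_first(p, "./time")), character(1))
  out <- data.frame(participant_id = participant_id, timestamp = parse_ts(tim),
                    lat = lat, lon = lon, elevation_m = ele,
                    stringsAsFactors = FALSE)
  if (anyNA(out$timestamp)) stop_input("GPX file: malformed <time> element")
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop_input("GPX file: coordinate out of range")
  }
  out <- out[order(out$timestamp), , drop = FALSE]
  if (anyDuplicated(out$timestamp)) stop_input("GPX file: duplicate timestamp")
  rownames(out) <- NULL
  out
}

#' Read an accelerometer count log
#'
#' Expects columns \code{participant_id,timestamp,counts} with one
#' non-negative integer count per 15 s epoch. Spacing other than 15 s
#' inside a recording is reported as missing epochs via a warning and the
#' \code{"gaps"} attribute of the result; no rows are dropped.
#'
#' @param path path to a CSV file
#' @return data.frame with columns participant_id, timestamp (POSIXct),
#'   counts (integer); attribute \code{gaps} holds one row per detected
#'   spacing irregularity (participant, after-timestamp, missing epochs)
#' @export
read_count_log <- function(path) {
  if (!file.exists(path)) stop_input("count log not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "timestamp", "counts"), "count log")
  ts <- parse_ts(df$timestamp)
  if (anyNA(ts)) {
    stop_input("count log: malformed timestamp at data row %d", which(is.na(ts))[1])
  }
  cnt <- suppressWarnings(as.numeric(df$counts))
  if (anyNA(cnt)) {
    stop_input("count log: malformed count at data row %d", which(is.na(cnt))[1])
  }
  if (any(cnt < 0)) {
    stop_input("count log: negative count at data row %d", which(cnt < 0)[1])
  }
  out <- data.frame(participant_id = df$participant_id, timestamp = ts,
                    counts = as.integer(round(cnt)), stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[c("participant_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_input("count log: duplicate timestamp %s for participant %s",
               format_ts(out$timestamp[i]), out$participant_id[i])
  }
  rownames(out) <- NULL
  gaps <- find_epoch_gaps(out, epoch_s = 15)
  if (nrow(gaps)) {
    warning(sprintf("count log: %d spacing irregularit%s (%d missing epochs); see attr(x, 'gaps')",
                    nrow(gaps), if (nrow(gaps) == 1) "y" else "ies",
                    sum(gaps$missing_epochs)), call. = FALSE)
  }
  attr(out, "gaps") <- gaps
  out
}

## locate spacing irregularities in a sorted epoch stream
find_epoch_gaps <- function(df, epoch_s) {
  if (nrow(df) < 2) {
    return(data.frame(participant_id = character(0),
                      after = as.POSIXct(character(0), tz = "UTC"),
                      gap_s = numeric(0), missing_epochs = integer(0)))
  }
  ## overnight breaks between recording days are structure, not data loss:
  ## only same-participant, same-date spacing counts as an irregularity
  same <- df$participant_id[-1] == df$participant_id[-nrow(df)] &
    ts_date(df$timestamp[-1]) == ts_date(df$timestamp[-nrow(df)])
  dt <- as.numeric(diff(df$timestamp), units = "secs")
  irr <- which(same & dt != epoch_s)
  data.frame(participant_id = df$participant_id[irr],
             after = df$timestamp[irr], gap_s = dt[irr],
             missing_epochs = pmax(0L, as.integer(round(dt[irr] / epoch_s)) - 1L),
             stringsAsFactors = FALSE)
}

#' Read the cohort (participant) table
#'
#' Validates all categorical fields against their allowed levels. Ages
#' outside 12--16 are flagged in the \code{age_in_range} column (the study
#' filter is applied downstream, not at parse time).
#'
#' @param path path to cohort.csv
#' @return validated data.frame
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "age", "gender", "ethnicity",
                      "education", "ses", "sport_club", "residence",
                      "home_lat", "home_lon", "school_id", "class_id"),
                "cohort table")
  df$participant_id <- as.character(df$participant_id)
  df$school_id <- as.character(df$school_id)
  df$class_id <- as.character(df$class_id)
  check_levels(df$gender, GENDER_LEVELS, "gender", "cohort table")
  check_levels(df$ethnicity, ETHNICITY_LEVELS, "ethnicity", "cohort table")
  check_levels(df$education, EDUCATION_LEVELS, "education", "cohort table")
  check_levels(df$ses, SES_LEVELS, "ses", "cohort table")
  check_levels(df$sport_club, YESNO_LEVELS, "sport_club", "cohort table")
  check_levels(df$residence, RESIDENCE_LEVELS, "residence", "cohort table")
  if (any(!is.finite(df$home_lat)) || any(!is.finite(df$home_lon))) {
    stop_input("cohort table: missing home coordinates")
  }
  df$age_in_range <- df$age >= 12 & df$age <= 16
  df
}

#' Read the school table
#' @param path path to schools.csv (school_id, lat, lon)
#' @return data.frame
#' @export
read_schools <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("school_id", "lat", "lon"), "school table")
  df$school_id <- as.character(df$school_id)
  df
}

#' Read class timetables (long CSV form)
#'
#' One row per block: \code{school_id,class_id,weekday,kind,start,end} with
#' weekday 1 (Monday) .. 7, kind one of \code{school}, \code{pe},
#' \code{recess}, and times as \code{HH:MM}. PE and recess blocks must nest
#' inside that weekday's school hours and blocks of the same class/day must
#' not overlap.
#'
#' @param path path to timetables.csv
#' @return validated data.frame with numeric start_min/end_min columns
#'   (minutes since midnight)
#' @export
read_timetables <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("school_id", "class_id", "weekday", "kind", "start",
                      "end"), "timetable")
  df$school_id <- as.character(df$school_id)
  df$class_id <- as.character(df$class_id)
  check_levels(df$kind, c("school", "pe", "recess"), "kind", "timetable")
  if (any(df$weekday < 1 | df$weekday > 7)) {
    stop_input("timetable: weekday must be 1 (Monday) .. 7")
  }
  hm <- function(x) {
    p <- strsplit(x, ":", fixed = TRUE)
    vapply(p, function(v) as.numeric(v[1]) * 60 + as.numeric(v[2]), numeric(1))
  }
  df$start_min <- hm(df$start)
  df$end_min <- hm(df$end)
  if (any(df$end_min <= df$start_min)) stop_input("timetable: block end before start")
  validate_timetable(df)
  df
}

validate_timetable <- function(tt) {
  key <- paste(tt$class_id, tt$weekday)
  for (k in unique(key)) {
    blk <- tt[key == k, , drop = FALSE]
    sch <- blk[blk$kind == "school", , drop = FALSE]
    sub <- blk[blk$kind != "school", , drop = FALSE]
    if (nrow(sub) && !nrow(sch)) {
      stop_input("timetable: %s block without school hours (class %s, weekday %s)",
                 sub$kind[1], sub$class_id[1], sub$weekday[1])
    }
    for (i in seq_len(nrow(sub))) {
      inside <- any(sub$start_min[i] >= sch$start_min & sub$end_min[i] <= sch$end_min)
      if (!inside) {
        stop_input("timetable: %s block %s-%s outside school hours (class %s, weekday %s)",
                   sub$kind[i], sub$start[i], sub$end[i], sub$class_id[i],
                   sub$weekday[i])
      }
    }
    if (nrow(sub) > 1) {
      o <- order(sub$start_min)
      s <- sub$start_min[o]; e <- sub$end_min[o]
      if (any(s[-1] < e[-length(e)])) {
        stop_input("timetable: overlapping PE/recess blocks (class %s, weekday %s)",
                   sub$class_id[1], sub$weekday[1])
      }
    }
  }
  invisible(tt)
}

#' Read POS annotations (interview product)
#'
#' One row per annotated stationary event: \code{participant_id,start,end,
#' pos_category,company,reasons,activities}. \code{company}, \code{reasons}
#' and \code{activities} are |-separated multi-response cells; company must
#' be non-empty and drawn from \code{\link{COMPANY_LEVELS}};
#' \code{pos_category} must be one of \code{\link{POS_CATEGORIES}}.
#'
#' @param path path to annotations.csv
#' @return validated data.frame with POSIXct start/end
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_columns(df, c("participant_id", "start", "end", "pos_category",
                      "company", "reasons", "activities"), "annotations")
  df$start <- parse_ts(df$start)
  df$end <- parse_ts(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop_input("annotations: malformed timestamp")
  if (any(df$end <= df$start)) stop_input("annotations: window end not after start")
  check_levels(df$pos_category, POS_CATEGORIES, "pos_category", "annotations")
  comp <- lapply(df$company, split_multi)
  if (any(lengths(comp) == 0)) {
    stop_input("annotations: empty company at data row %d",
               which(lengths(comp) == 0)[1])
  }
  check_levels(unlist(comp), COMPANY_LEVELS, "company", "annotations")
  df
}

#' Read the daily weather table
#' @param path path to weather.csv (date, rain_mm, sun_min, temp_c)
#' @return validated data.frame with Date column
#' @export
read_weather <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("date", "rain_mm", "sun_min", "temp_c"), "weather")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_input("weather: malformed date")
  if (any(df$rain_mm < 0)) stop_input("weather: negative rainfall")
  if (any(df$sun_min < 0)) stop_input("weather: negative sunshine")
  df
}

## writers (canonical dialects; used by the simulator and for audit output)

write_ts_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a simulated or field dataset directory
#'
#' Loads the six pipeline input files (\code{gps.csv}, \code{counts.csv},
#' \code{cohort.csv}, \code{schools.csv}, \code{timetables.csv},
#' \code{annotations.csv}, \code{weather.csv}) from \code{dir}. Any ground
#' truth file the simulator may have written alongside them
#' (\code{ground_truth*.csv}) is never read here: the pipeline consumes
#' observable data only.
#'
#' @param dir directory holding the canonical CSVs
#' @return named list of validated tables
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(gps = read_gps_log(p("gps.csv")),
       counts = read_count_log(p("counts.csv")),
       cohort = read_cohort(p("cohort.csv")),
       schools = read_schools(p("schools.csv")),
       timetables = read_timetables(p("timetables.csv")),
       annotations = read_annotations(p("annotations.csv")),
       weather = read_weather(p("weather.csv")))
}
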