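## internal helpers shared across modules

TS_FORMAT <- "%Y-%m-%d %H:%M:%S"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse ISO-8601 local timestamps
#'
#' Timestamps carry no zone offset; the whole study is assumed to live in
#' one local civil time, so they are stored internally as UTC.
#' @param x character vector of "YYYY-MM-DD HH:MM:SS" strings (a "T"
#'   separator and a trailing "Z" are tolerated).
#' @return POSIXct vector
#' @keywords internal
parse_ts <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
}

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

## local civil date of a timestamp
ts_date <- function(x) as.Date(x, tz = "UTC")

## minutes since local midnight
ts_tod_min <- function(x) {
  as.numeric(difftime(x, as.POSIXct(paste(ts_date(x), "00:00:00"), tz = "UTC"),
                      units = "mins"))
}

## ISO weekday, 1 = Monday ... 7 = Sunday
ts_weekday <- function(d) {
  w <- as.integer(format(as.Date(d), "%u"))
  w
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input("%s: missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_levels <- function(x, levels, field, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad)) {
    stop_input("%s: unknown %s level(s) %s; allowed: %s", what, field,
               paste(sQuote(bad), collapse = ", "),
               paste(levels, collapse = ", "))
  }
  invisible(x)
}

## split a "a|b|c" multi-response cell into a character vector
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

join_multi <- function(x) paste(x, collapse = "|")

## derive a reproducible per-unit seed from a master seed (SplitMix-style
## integer hash, kept in [0, 2^31))
derive_seed <- function(master, index) {
  x <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503) %% 2147483647
  h <- (x * 2246822519) %% 2147483647
  as.integer(h)
}
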