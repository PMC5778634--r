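## Per-participant aggregation (the analysis input) and cohort-level
## descriptives (prevalence, context and company of POS visitation).

#' Build per-participant summaries over valid days
#'
#' Per-day means are computed over valid days only (>= 9 h worn by
#' default, applied upstream via \code{\link{select_valid}}). POS
#' intensity minutes include the minutes accumulated on attributed trips
#' to and from POS. Company counts increment once per visit per reported
#' company category, so multi-company visits increment several.
#'
#' @param visits visit table (\code{\link{extract_pos_visits}})
#' @param epochs worn/classified count epoch table (\code{\link{flag_wear}})
#' @param wear valid-day table from \code{\link{select_valid}}
#' @param cohort cohort table
#' @param weather daily weather table (optional)
#' @param epoch_s count epoch length in seconds
#' @return one row per included participant: n_days, wear_min_day,
#'   used_pos, pos_visits_day, st/lpa/mpa/vpa/mvpa_min_day (totals),
#'   pos_min_day, pos_st/lpa/mpa/vpa/mvpa_min_day, visits_<company>,
#'   demographics and weather means
#' @export
summarize_participants <- function(visits, epochs, wear, cohort,
                                   weather = NULL, epoch_s = 15) {
  included <- attr(wear, "included")
  if (is.null(included)) stop_input("summarize_participants: run select_valid first")
  valid <- wear[wear$valid, , drop = FALSE]
  epochs$date <- ts_date(epochs$timestamp)
  epochs$intensity <- classify_intensity(epochs$counts)
  vkey <- paste(valid$participant_id, valid$date)
  ep <- epochs[paste(epochs$participant_id, epochs$date) %in% vkey &
                 epochs$worn, , drop = FALSE]
  vis <- visits[paste(visits$participant_id, visits$date) %in% vkey, , drop = FALSE]

  rows <- lapply(included, function(pid) {
    vd <- valid[valid$participant_id == pid, , drop = FALSE]
    nd <- nrow(vd)
    e <- ep[ep$participant_id == pid, , drop = FALSE]
    v <- vis[vis$participant_id == pid, , drop = FALSE]
    tot <- function(cls) sum(e$intensity == cls) * epoch_s / 60 / nd
    r <- data.frame(participant_id = pid, n_days = nd,
                    wear_min_day = mean(vd$wear_min),
                    pos_visits_day = nrow(v) / nd,
                    used_pos = nrow(v) > 0,
                    st_min_day = tot("sedentary"), lpa_min_day = tot("light"),
                    mpa_min_day = tot("moderate"), vpa_min_day = tot("vigorous"),
                    stringsAsFactors = FALSE)
    r$mvpa_min_day <- r$mpa_min_day + r$vpa_min_day
    r$pos_min_day <- sum(v$total_min) / nd
    r$pos_st_min_day <- sum(v$st_min) / nd
    r$pos_lpa_min_day <- sum(v$lpa_min) / nd
    r$pos_mpa_min_day <- sum(v$mpa_min) / nd
    r$pos_vpa_min_day <- sum(v$vpa_min) / nd
    r$pos_mvpa_min_day <- sum(v$mvpa_min) / nd
    comp <- unlist(lapply(v$company, split_multi))
    for (lev in COMPANY_LEVELS) {
      col <- paste0("visits_", company_slug(lev))
      r[[col]] <- sum(comp == lev)
    }
    if (!is.null(weather)) {
      w <- weather[weather$date %in% vd$date, , drop = FALSE]
      r$rain_mm <- mean(w$rain_mm); r$sun_min <- mean(w$sun_min)
      r$temp_c <- mean(w$temp_c)
    }
    r
  })
  out <- do.call(rbind, rows)
  ci <- match(out$participant_id, cohort$participant_id)
  for (col in c("age", "gender", "ethnicity", "education", "ses",
                "sport_club", "residence", "school_id", "class_id")) {
    if (col %in% names(cohort)) out[[col]] <- cohort[[col]][ci]
  }
  rownames(out) <- NULL
  out
}

company_slug <- function(x) {
  c("friends/classmates" = "friends", "siblings/cousins" = "siblings",
    "parents/grandparents" = "parents", "alone" = "alone",
    "organisation" = "organisation")[[x]]
}

#' Cohort-level descriptive report
#'
#' Mirrors the usual descriptive layout for POS-visitation studies: the
#' share of participants who used a POS, visit frequency among users,
#' visit percentages by company (multi-response, may exceed 100), by POS
#' category (single-response, sums to 100 up to rounding), by reason and
#' activity (multi-response), and median/quartiles of the skewed
#' outcomes.
#'
#' @param summaries participant summaries
#'   (\code{\link{summarize_participants}})
#' @param visits visit table restricted to valid days
#' @return list of class \code{pos_descriptives}
#' @export
cohort_descriptives <- function(summaries, visits) {
  if (!nrow(summaries)) stop_input("cohort_descriptives: empty cohort")
  n_vis <- nrow(visits)
  multi_pct <- function(cells, levels = NULL) {
    items <- unlist(lapply(cells, split_multi))
    tab <- table(items)
    p <- as.numeric(tab) / max(1, n_vis) * 100
    names(p) <- names(tab)
    if (!is.null(levels)) {
      p <- setNames(ifelse(levels %in% names(p), p[levels], 0), levels)
    }
    sort(p, decreasing = TRUE)
  }
  cat_tab <- table(factor(visits$pos_category, levels = POS_CATEGORIES))
  qs <- function(x) setNames(quantile(x, c(0.5, 0.25, 0.75)), c("median", "q1", "q3"))
  users <- summaries[summaries$used_pos, , drop = FALSE]
  res <- list(
    n_participants = nrow(summaries),
    n_visits = n_vis,
    pct_pos_users = mean(summaries$used_pos) * 100,
    mean_visits_day_users = if (nrow(users)) mean(users$pos_visits_day) else NA_real_,
    pct_by_company = multi_pct(visits$company, COMPANY_LEVELS),
    pct_by_category = setNames(as.numeric(cat_tab) / max(1, n_vis) * 100,
                               names(cat_tab)),
    pct_by_reason = multi_pct(visits$reasons),
    pct_by_activity = multi_pct(visits$activities),
    mvpa_min_day = qs(summaries$mvpa_min_day),
    pos_min_day_users = if (nrow(users)) qs(users$pos_min_day) else NULL,
    mean_age = mean(summaries$age %||% NA_real_),
    pct_girls = if ("gender" %in% names(summaries))
      mean(summaries$gender == "female") * 100 else NA_real_
  )
  class(res) <- "pos_descriptives"
  res
}

#' @export
print.pos_descriptives <- function(x, ...) {
  cat(sprintf("POS-use descriptives: %d participants, %d POS visits\n",
              x$n_participants, x$n_visits))
  cat(sprintf("  %% of participants who used a POS: %.1f\n", x$pct_pos_users))
  cat(sprintf("  mean POS visits/day among users:  %.2f\n",
              x$mean_visits_day_users))
  cat("  visits by company (%, multi-response):\n")
  for (nm in names(x$pct_by_company)) {
    cat(sprintf("    %-28s %5.1f\n", nm, x$pct_by_company[[nm]]))
  }
  cat("  visits by POS category (%):\n")
  for (nm in names(sort(x$pct_by_category, decreasing = TRUE))) {
    cat(sprintf("    %-36s %5.1f\n", nm, x$pct_by_category[[nm]]))
  }
  cat(sprintf("  MVPA min/day: median %.1f (Q1 %.1f, Q3 %.1f)\n",
              x$mvpa_min_day[["median"]], x$mvpa_min_day[["q1"]],
              x$mvpa_min_day[["q3"]]))
  invisible(x)
}

#' Write the descriptive report as CSV
#' @param x \code{pos_descriptives} object
#' @param path output file
#' @return path, invisibly
#' @export
write_descriptives_csv <- function(x, path) {
  rows <- rbind(
    data.frame(section = "sample", item = "pct_pos_users",
               value = x$pct_pos_users),
    data.frame(section = "sample", item = "mean_visits_day_users",
               value = x$mean_visits_day_users),
    data.frame(section = "company", item = names(x$pct_by_company),
               value = as.numeric(x$pct_by_company)),
    data.frame(section = "category", item = names(x$pct_by_category),
               value = as.numeric(x$pct_by_category)),
    data.frame(section = "reason", item = names(x$pct_by_reason),
               value = as.numeric(x$pct_by_reason)),
    data.frame(section = "activity", item = names(x$pct_by_activity),
               value = as.numeric(x$pct_by_activity))
  )
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
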