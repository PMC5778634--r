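## End-to-end orchestration: raw streams -> fused epochs -> segments ->
## POS visits -> participant summaries -> descriptives.

#' Run the processing pipeline on loaded tables
#'
#' Executes wear detection, stream fusion, plausibility filtering,
#' movement classification, optional interview corrections, domain
#' assignment, consolidation, annotation join, POS-visit extraction,
#' valid-day filtering and per-participant aggregation.
#'
#' @param data named list as from \code{\link{read_dataset}} or a
#'   \code{pos_simulation}
#' @param corrections optional movement-correction table
#'   (\code{\link{apply_corrections}})
#' @param nonwear_min non-wear run threshold, minutes (default 60)
#' @param valid_day_min valid-day wear threshold, minutes (default 540)
#' @param max_speed_kmh,max_jump_m,max_elev_m plausibility thresholds
#' @param buffer_m home/school buffer radius, metres (default 100)
#' @param smooth_epochs movement-flicker absorption (default 1)
#' @return list of class \code{pos_pipeline}: epochs, fused, segments,
#'   visits, wear, summaries, descriptives
#' @export
run_pipeline <- function(data, corrections = NULL, nonwear_min = 60,
                         valid_day_min = 540, max_speed_kmh = 130,
                         max_jump_m = 1000, max_elev_m = 100,
                         buffer_m = 100, smooth_epochs = 1) {
  epochs <- flag_wear(data$counts, nonwear_min = nonwear_min)
  fused <- align_streams(data$gps, epochs)
  fused <- flag_invalid_fixes(fused, max_speed_kmh = max_speed_kmh,
                              max_jump_m = max_jump_m,
                              max_elev_m = max_elev_m)
  fused <- add_movement(fused, smooth_epochs = smooth_epochs)
  if (!is.null(corrections)) fused <- apply_corrections(fused, corrections)
  fused <- assign_domain(fused, data$cohort, data$schools, data$timetables,
                         buffer_m = buffer_m)
  segments <- consolidate(fused)
  segments <- join_annotations(segments, data$annotations)
  visits <- extract_pos_visits(segments)
  wear <- select_valid(wear_by_day(epochs), valid_day_min = valid_day_min)
  summaries <- summarize_participants(visits, epochs, wear, data$cohort,
                                      weather = data$weather)
  vkey <- paste(visits$participant_id, visits$date)
  wkey <- paste(wear$participant_id[wear$valid], wear$date[wear$valid])
  descriptives <- cohort_descriptives(summaries,
                                      visits[vkey %in% wkey, , drop = FALSE])
  out <- list(epochs = epochs, fused = fused, segments = segments,
              visits = visits, wear = wear, summaries = summaries,
              descriptives = descriptives)
  class(out) <- "pos_pipeline"
  out
}

#' Write pipeline audit tables to a directory
#'
#' Emits the fused-epoch, segment, visit and participant-summary tables
#' as CSV for audit and model input.
#'
#' @param result \code{pos_pipeline} object
#' @param dir output directory
#' @return dir, invisibly
#' @export
write_pipeline_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  seg <- result$segments
  write_ts_csv(seg[c("participant_id", "date", "kind", "label", "start",
                     "end", "duration_min", "st_min", "lpa_min", "mpa_min",
                     "vpa_min", "pos_category")], p("segments.csv"))
  write_ts_csv(result$visits, p("visits.csv"))
  write_ts_csv(result$summaries, p("participant_summary.csv"))
  write_descriptives_csv(result$descriptives, p("descriptives.csv"))
  invisible(dir)
}
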