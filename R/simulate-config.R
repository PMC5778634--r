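## Simulation configuration: the study conditions the generator emulates.
## Defaults mirror the measurement design of a one-city adolescent cohort:
## 30 s GPS logging, 15 s count epochs, school-clustered participants,
## zero-heavy right-skewed POS time, and mode speeds sitting well inside
## the pedestrian / bicycle / motorized bands.

#' Build a simulation configuration
#'
#' All arguments have defaults chosen to emulate a Belgian urban adolescent
#' cohort: demographics follow realistic marginals (54.4%
#' girls, mean age 14.2, 28.3% non-western-European, education mix
#' general/vocational/technical, 58% sport-club members, mostly urban),
#' POS-site categories follow the observed visit mix (transit stops
#' dominate), and the POS-outcome process is a two-part model -- a daily
#' visit probability on the logit scale and a gamma dwell time on the log
#' scale -- with school-level normal random intercepts.
#'
#' @param n_participants,n_schools,n_days cohort dimensions
#' @param start_date first study date (a Monday); day 1 is a school day,
#'   day 2 a weekend day, further days alternate through the week
#' @param study_area named bounding box (lat_min, lat_max, lon_min,
#'   lon_max), decimal degrees WGS84
#' @param n_pos_sites number of POS sites scattered over the study area
#' @param pos_category_probs site-choice probabilities over the nine POS
#'   categories
#' @param demographics list of marginals (see defaults)
#' @param behaviour list of behavioural parameters: mode speeds (km/h),
#'   trip-mode choice, per-context count regimes and the lognormal count
#'   distribution of each intensity regime, daily POS visit probability
#'   (reference participant), extra-visit Poisson rate, gamma dwell
#'   (shape, mean minutes), company/reason/activity probabilities,
#'   non-wear and GPS-dropout injection, GPS jitter, wake/sleep times
#' @param effects list with named coefficient vectors \code{occurrence}
#'   (log-odds) and \code{amount} (log-minutes) over covariate columns
#'   (gender_female, age_c, ethnicity_nonwestern, education_technical,
#'   education_vocational, ses_low, sport_club_yes, residence_suburban,
#'   residence_urban) and \code{school_sigma}, the SD of the school
#'   random intercepts
#' @param seed master seed; all per-participant streams derive from it by
#'   counter-based splitting, so generation is order-independent
#' @return validated list of class \code{sim_config}
#' @export
sim_config <- function(n_participants = 50,
                       n_schools = 6,
                       n_days = 2,
                       start_date = as.Date("2015-09-14"),
                       study_area = c(lat_min = 51.00, lat_max = 51.10,
                                      lon_min = 3.65, lon_max = 3.80),
                       n_pos_sites = 40,
                       pos_category_probs = default_pos_category_probs(),
                       demographics = default_demographics(),
                       behaviour = default_behaviour(),
                       effects = default_effects(),
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_schools = as.integer(n_schools),
              n_days = as.integer(n_days),
              start_date = as.Date(start_date),
              study_area = study_area,
              n_pos_sites = as.integer(n_pos_sites),
              pos_category_probs = pos_category_probs,
              demographics = utils::modifyList(default_demographics(), demographics),
              behaviour = utils::modifyList(default_behaviour(), behaviour),
              effects = utils::modifyList(default_effects(), effects),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

default_pos_category_probs <- function() {
  setNames(c(0.710, 0.094, 0.054, 0.035, 0.032, 0.029, 0.029, 0.013, 0.004),
           POS_CATEGORIES)
}

default_demographics <- function() {
  list(age_mean = 14.2, age_sd = 1.1, age_range = c(12, 16),
       p_girl = 0.544, p_nonwestern = 0.283,
       education_probs = c(general = 0.688, vocational = 0.220,
                           technical = 0.092),
       p_low_ses = 0.225, p_sport_club = 0.580,
       residence_probs = c(rural = 0.069, suburban = 0.168, urban = 0.763))
}

default_behaviour <- function() {
  list(
    mode_speed_kmh = c(pedestrian = 5, bicycle = 16, motorized = 40),
    mode_probs = c(pedestrian = 0.40, bicycle = 0.40, motorized = 0.20),
    regime_lognormal = list(
      sedentary = c(meanlog = log(20), sdlog = 1.00),
      light     = c(meanlog = log(600), sdlog = 0.45),
      moderate  = c(meanlog = log(2950), sdlog = 0.12),
      vigorous  = c(meanlog = log(5200), sdlog = 0.15)),
    context_regimes = list(
      home          = c(sedentary = 0.80, light = 0.18, moderate = 0.02, vigorous = 0.00),
      school_class  = c(0.90, 0.10, 0.00, 0.00),
      school_pe     = c(0.10, 0.20, 0.50, 0.20),
      school_recess = c(0.30, 0.50, 0.15, 0.05),
      pos_sedentary = c(0.60, 0.37, 0.02, 0.01),
      pos_active    = c(0.25, 0.40, 0.25, 0.10),
      pedestrian    = c(0.05, 0.75, 0.20, 0.00),
      bicycle       = c(0.05, 0.35, 0.50, 0.10),
      motorized     = c(0.90, 0.10, 0.00, 0.00)),
    active_pos_categories = c("park", "sport field/playground", "square"),
    pos_visit_prob = 0.50,
    visits_extra_pois = 0.8,
    dwell_shape = 2, dwell_mean_min = 25,
    company_probs = c("friends/classmates" = 0.598, "siblings/cousins" = 0.164,
                      "parents/grandparents" = 0.164, "alone" = 0.156,
                      "organisation" = 0.025),
    reason_probs = c("wait for something/someone" = 0.303,
                     "friends/siblings wanted to go" = 0.174,
                     "other" = 0.174, "close to home/school" = 0.138,
                     "decided to stay" = 0.101, "habit" = 0.083,
                     "nice atmosphere" = 0.046, "sport infrastructure" = 0.046),
    activity_probs = c("standing" = 0.431, "walking" = 0.385,
                       "sitting/lying down" = 0.138, "ball sports" = 0.064,
                       "biking" = 0.028, "other" = 0.018),
    nonwear_prob = 0.15, nonwear_min_range = c(60, 120),
    dropout_prob = 0.20, dropout_min_range = c(5, 20),
    gps_jitter_m = 2,
    wake_min = 450, sleep_min = 1290  # 07:30 -- 21:30 local
  )
}

default_effects <- function() {
  list(occurrence = c(gender_female = -0.4, age_c = -0.3,
                      ethnicity_nonwestern = 0.8),
       amount = c(gender_female = -0.5),
       school_sigma = 0.4)
}

#' Validate a simulation configuration
#' @param cfg list as from \code{\link{sim_config}}
#' @return cfg invisibly; errors on violation
#' @export
validate_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_input("config: need at least one participant")
  if (cfg$n_schools < 1) stop_input("config: need at least one school")
  if (cfg$n_days < 1) stop_input("config: need at least one day")
  b <- cfg$behaviour
  sp <- b$mode_speed_kmh
  if (!(sp[["pedestrian"]] >= 1 && sp[["pedestrian"]] < 10)) {
    stop_input("config: pedestrian speed must lie in [1, 10) km/h")
  }
  if (!(sp[["bicycle"]] >= 10 && sp[["bicycle"]] < 25)) {
    stop_input("config: bicycle speed must lie in [10, 25) km/h")
  }
  if (sp[["motorized"]] < 25) stop_input("config: motorized speed must be >= 25 km/h")
  if (!(sp[["pedestrian"]] < sp[["bicycle"]] && sp[["bicycle"]] < sp[["motorized"]])) {
    stop_input("config: mode speeds must be ordered pedestrian < bicycle < motorized")
  }
  probs <- c(b$pos_visit_prob, b$nonwear_prob, b$dropout_prob,
             b$company_probs, b$mode_probs, cfg$pos_category_probs,
             unlist(b$context_regimes))
  if (any(probs < 0 | probs > 1)) stop_input("config: probabilities must lie in [0, 1]")
  if (b$dwell_mean_min <= 0 || b$dwell_shape <= 0) {
    stop_input("config: dwell-time distribution must be strictly positive")
  }
  if (cfg$effects$school_sigma < 0) stop_input("config: school_sigma must be >= 0")
  invisible(cfg)
}

## design-matrix row (named numeric) used by both the generator and the
## recovery experiments
covariate_row <- function(p, age_center) {
  c(gender_female = as.numeric(p$gender == "female"),
    age_c = p$age - age_center,
    ethnicity_nonwestern = as.numeric(p$ethnicity == "non-western-European"),
    education_technical = as.numeric(p$education == "technical"),
    education_vocational = as.numeric(p$education == "vocational"),
    ses_low = as.numeric(p$ses == "low"),
    sport_club_yes = as.numeric(p$sport_club == "yes"),
    residence_suburban = as.numeric(p$residence == "suburban"),
    residence_urban = as.numeric(p$residence == "urban"))
}

lin_pred <- function(x, beta) {
  if (!length(beta)) return(0)
  miss <- setdiff(names(beta), names(x))
  if (length(miss)) stop_input("unknown effect covariate: %s", miss[1])
  sum(x[names(beta)] * beta)
}
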