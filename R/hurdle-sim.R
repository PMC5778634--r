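## Summary-level simulator for the two-part model: draws participant
## summaries directly from the hurdle data-generating process (logistic
## occurrence, gamma amount, school random intercepts). Used for the
## parameter-recovery, coverage and type-I-error experiments, where the
## model layer is exercised at sample sizes the trajectory-level
## generator is not meant for.

#' Simulate participant summaries from the hurdle process
#'
#' Demographics are drawn from the same marginals as the trajectory-level
#' generator; the outcome is \code{pos_min_day} with
#' \code{P(use) = plogis(qlogis(p0) + x'b_occ + u_school)} and positive
#' amounts gamma-distributed with mean
#' \code{exp(log(mu0) + x'b_amt + v_school)}.
#'
#' @param n participants
#' @param n_schools schools (balanced assignment)
#' @param beta_occ named log-odds coefficients over covariate columns
#'   (see \code{\link{sim_config}} effects)
#' @param beta_amt named log-minute coefficients
#' @param p0 occurrence probability at the reference covariates
#' @param mu0 mean positive minutes at the reference covariates
#' @param shape gamma shape
#' @param school_sigma SD of the (independent) school intercepts of both
#'   parts
#' @param demographics marginals list (default as in
#'   \code{\link{sim_config}})
#' @param seed integer seed
#' @return data.frame with demographics, school_id, used_pos,
#'   pos_min_day; attribute \code{truth} echoes the generating
#'   parameters
#' @export
simulate_hurdle_data <- function(n = 1000, n_schools = 6,
                                 beta_occ = c(gender_female = -0.4),
                                 beta_amt = c(gender_female = -0.5),
                                 p0 = 0.5, mu0 = 25, shape = 2,
                                 school_sigma = 0.4,
                                 demographics = default_demographics(),
                                 seed = 1L) {
  set.seed(seed)
  d <- demographics
  age <- pmin(d$age_range[2], pmax(d$age_range[1],
                                   rnorm(n, d$age_mean, d$age_sd)))
  df <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    gender = ifelse(runif(n) < d$p_girl, "female", "male"),
    ethnicity = ifelse(runif(n) < d$p_nonwestern, "non-western-European",
                       "western-European"),
    education = sample(names(d$education_probs), n, replace = TRUE,
                       prob = d$education_probs),
    ses = ifelse(runif(n) < d$p_low_ses, "low", "high"),
    sport_club = ifelse(runif(n) < d$p_sport_club, "yes", "no"),
    residence = sample(names(d$residence_probs), n, replace = TRUE,
                       prob = d$residence_probs),
    school_id = sprintf("S%d", rep_len(seq_len(n_schools), n)),
    stringsAsFactors = FALSE)
  u <- rnorm(n_schools, 0, school_sigma)
  v <- rnorm(n_schools, 0, school_sigma)
  si <- rep_len(seq_len(n_schools), n)
  xb_occ <- numeric(n); xb_amt <- numeric(n)
  for (i in seq_len(n)) {
    x <- covariate_row(df[i, ], d$age_mean)
    xb_occ[i] <- lin_pred(x, beta_occ)
    xb_amt[i] <- lin_pred(x, beta_amt)
  }
  p_use <- plogis(qlogis(p0) + xb_occ + u[si])
  used <- runif(n) < p_use
  mu <- exp(log(mu0) + xb_amt + v[si])
  amt <- rgamma(n, shape = shape, rate = shape / mu)
  df$used_pos <- used
  df$pos_min_day <- ifelse(used, amt, 0)
  attr(df, "truth") <- list(beta_occ = beta_occ, beta_amt = beta_amt,
                            p0 = p0, mu0 = mu0, shape = shape,
                            school_sigma = school_sigma)
  df
}
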