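## The four-step model-building procedure: screen covariates, test each
## individual factor separately, combine the significant ones, then test
## each social-environment variable adjusted for those factors.

#' Stepwise model building for one POS outcome
#'
#' Step 1 screens the candidate covariates (all entered simultaneously;
#' retained at p < alpha; per-outcome forced covariates always kept).
#' Step 2 enters each individual factor separately into a
#' covariate-adjusted model. Step 3 enters the factors significant in
#' step 2 together (significance means p < alpha in either hurdle part;
#' trends at p < 0.1 are reported but never move a factor forward).
#' Step 4 enters each social-environment variable separately, adjusted
#' for the step-3 factors and covariates; when step 3 is empty, step 4
#' adjusts for covariates only and the report notes it.
#'
#' @param data participant summary table
#' @param outcome outcome column (e.g. pos_min_day, pos_mvpa_min_day)
#' @param individual_factors character vector (default: age, gender,
#'   ethnicity, education, sport_club)
#' @param social_factors character vector (default: per-company visit
#'   counts except organisation)
#' @param covariate_candidates candidates for step-1 screening
#' @param forced_covariates covariates always retained (e.g. the matching
#'   total-intensity term for an intensity outcome)
#' @param hurdle fit both parts (TRUE, for outcomes with structural
#'   zeros) or the gamma amount part only on the POS-user subset (FALSE)
#' @param alpha significance level (default 0.05)
#' @param group random-intercept grouping column
#' @return object of class \code{pos_stepwise}: \code{$covariates},
#'   \code{$step2}, \code{$step3}, \code{$step4}, \code{$table} (tidy
#'   report rows), \code{$notes}
#' @export
stepwise_procedure <- function(data, outcome,
                               individual_factors = c("age", "gender",
                                                      "ethnicity",
                                                      "education",
                                                      "sport_club"),
                               social_factors = c("visits_friends",
                                                  "visits_siblings",
                                                  "visits_parents",
                                                  "visits_alone"),
                               covariate_candidates = c("residence",
                                                        "wear_min_day",
                                                        "pos_visits_day",
                                                        "n_days", "rain_mm",
                                                        "sun_min", "temp_c"),
                               forced_covariates = character(),
                               hurdle = TRUE, alpha = 0.05,
                               group = "school_id") {
  notes <- character()
  fitdat <- if (hurdle) data else data[data$used_pos, , drop = FALSE]
  covariate_candidates <- intersect(covariate_candidates, names(data))
  covs <- screen_covariates(fitdat, outcome, covariate_candidates,
                            forced = forced_covariates, alpha = alpha,
                            group = group)

  fit_one <- function(terms, d = fitdat, drop_occ = character()) {
    if (hurdle) {
      ## mean POS visits/day and the per-company visit counts separate the
      ## occurrence indicator by construction (any visit implies use):
      ## they enter the amount part only
      fit_hurdle(d, outcome, terms, group = group,
                 drop_occurrence = c("pos_visits_day", drop_occ))
    } else {
      pos <- d[d[[outcome]] > 0, , drop = FALSE]
      fit <- fit_glmm(pos, outcome, terms, part = "amount", group = group)
      structure(list(outcome = outcome, occurrence = NULL, amount = fit,
                     notes = character(), logLik = fit$logLik),
                class = "pos_hurdle")
    }
  }

  step2 <- lapply(individual_factors, function(f)
    fit_one(c(f, covs)))
  names(step2) <- individual_factors

  sig2 <- vapply(individual_factors, function(f) {
    factor_significant(step2[[f]], f, fitdat, alpha)
  }, logical(1))

  step3 <- NULL
  selected <- individual_factors[sig2]
  if (length(selected)) {
    step3 <- fit_one(c(selected, covs))
  } else {
    notes <- c(notes, "step 3 empty: no individual factor significant; step 4 adjusts for covariates only")
  }

  social_factors <- intersect(social_factors, names(data))
  step4 <- lapply(social_factors, function(s)
    fit_one(c(s, selected, covs), drop_occ = s))
  names(step4) <- social_factors

  out <- list(outcome = outcome, covariates = covs, step2 = step2,
              selected_factors = selected, step3 = step3, step4 = step4,
              alpha = alpha, hurdle = hurdle, notes = notes)
  out$table <- stepwise_table(out)
  class(out) <- "pos_stepwise"
  out
}

factor_significant <- function(hfit, fct, data, alpha) {
  for (part in list(hfit$occurrence, hfit$amount)) {
    if (is.null(part)) next
    rows <- term_rows(part$coefficients$term, fct, data)
    if (length(rows) && any(part$coefficients$p[rows] < alpha, na.rm = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

stepwise_table <- function(x) {
  rows <- list()
  add <- function(step, label, hfit) {
    for (part in list(hfit$occurrence, hfit$amount)) {
      if (is.null(part)) next
      tab <- part$coefficients
      rows[[length(rows) + 1]] <<- data.frame(
        outcome = x$outcome, step = step, model = label, part = part$part,
        term = tab$term, estimate = tab$estimate, se = tab$se,
        exp_estimate = tab$exp_estimate, ci_low = tab$ci_low,
        ci_high = tab$ci_high, p = tab$p, marker = sig_marker(tab$p),
        n = part$n, stringsAsFactors = FALSE)
    }
  }
  for (f in names(x$step2)) add("step2", f, x$step2[[f]])
  if (!is.null(x$step3)) add("step3", "joint", x$step3)
  for (s in names(x$step4)) add("step4", s, x$step4[[s]])
  do.call(rbind, rows)
}

#' @export
print.pos_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise models for %s (alpha = %.2f)\n", x$outcome, x$alpha))
  cat(sprintf("  covariates retained: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  cat(sprintf("  step-3 factors: %s\n",
              if (length(x$selected_factors))
                paste(x$selected_factors, collapse = ", ") else "(none)"))
  tab <- x$table[x$table$term != "(Intercept)", ]
  print(format(tab[c("step", "model", "part", "term", "exp_estimate",
                     "ci_low", "ci_high", "p", "marker")], digits = 3),
        row.names = FALSE)
  if (length(x$notes)) cat(paste0("note: ", x$notes, "\n"))
  invisible(x)
}

#' Write a stepwise model report as CSV
#' @param x \code{pos_stepwise} object
#' @param path output file
#' @return path, invisibly
#' @export
write_model_csv <- function(x, path) {
  write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
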