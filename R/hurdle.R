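## Two-part multilevel models for zero-heavy POS outcomes: a logistic
## occurrence part (did the participant use a POS at all?) on the full
## cohort and a gamma log-link amount part (how many minutes?) on the
## positive subset, each with a normal school random intercept estimated
## by Laplace-approximate maximum likelihood.

#' Prepare participant summaries for modelling
#'
#' Converts categorical columns to factors with the study's reference
#' levels (male, general education, western-European, sport-club member,
#' urban residence).
#'
#' @param data participant summary table
#' @return data.frame ready for \code{\link{fit_glmm}}
#' @export
prepare_model_data <- function(data) {
  relev <- list(gender = GENDER_LEVELS, education = EDUCATION_LEVELS,
                ethnicity = ETHNICITY_LEVELS, sport_club = YESNO_LEVELS,
                ses = c("high", "low"),
                residence = c("urban", "suburban", "rural"))
  for (col in names(relev)) {
    if (col %in% names(data)) data[[col]] <- factor(data[[col]], relev[[col]])
  }
  if ("school_id" %in% names(data)) data$school_id <- factor(data$school_id)
  data
}

#' Fit one part of a multilevel hurdle model
#'
#' Occurrence part: logistic GLMM on the indicator \code{outcome > 0},
#' fitted to all rows. Amount part: gamma GLMM with log link fitted to the
#' rows with \code{outcome > 0} (an explicit zero in the amount part is an
#' input error). Both use a normal random intercept per grouping unit,
#' Laplace-approximate ML, Wald standard errors and
#' \code{exp(beta +/- z * SE)} confidence intervals. Exponentiated
#' coefficients are odds ratios (occurrence) or proportional differences
#' in minutes (amount).
#'
#' @param data model data (\code{\link{prepare_model_data}})
#' @param outcome outcome column name
#' @param covariates character vector of fixed-effect terms (may be empty)
#' @param part "occurrence" or "amount"
#' @param group grouping column for the random intercept (default
#'   school_id)
#' @param conf_level Wald CI level (default 0.95)
#' @return object of class \code{pos_glmm}: coefficient table
#'   (\code{$coefficients}), \code{$n}, \code{$ranef_var}, \code{$logLik},
#'   the underlying fit in \code{$model}
#' @export
fit_glmm <- function(data, outcome, covariates = character(),
                     part = c("occurrence", "amount"), group = "school_id",
                     conf_level = 0.95) {
  part <- match.arg(part)
  data <- prepare_model_data(data)
  y <- data[[outcome]]
  if (is.null(y)) stop_input("fit_glmm: outcome %s not in data", outcome)
  if (part == "occurrence") {
    data$.y <- as.numeric(y > 0)
    fam <- binomial(link = "logit")
  } else {
    if (any(y <= 0)) {
      stop_input("fit_glmm: amount part requires strictly positive outcomes (%d zeros present); fit on the positive subset",
                 sum(y <= 0))
    }
    data$.y <- y
    fam <- Gamma(link = "log")
  }
  if (length(unique(data[[group]])) < 2) {
    stop_input("fit_glmm: need at least 2 grouping units in %s", group)
  }
  rhs <- paste(c(if (length(covariates)) covariates else "1",
                 sprintf("(1 | %s)", group)), collapse = " + ")
  form <- as.formula(paste(".y ~", rhs))
  ## the inner optimizer may probe invalid parameter values on its way to
  ## the optimum; that transient NA/NaN warning carries no information
  fit <- withCallingHandlers(
    glmmTMB::glmmTMB(form, data = data, family = fam),
    warning = function(w) {
      if (grepl("NA/NaN function evaluation", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  grad <- tryCatch(max(abs(fit$obj$gr(fit$fit$par))), error = function(e) NA)
  pd <- isTRUE(fit$sdr$pdHess)
  if (!pd) {
    stop(sprintf("fit_glmm: %s part did not converge (non-positive-definite Hessian; max |gradient| = %.3g; optimizer: %s)",
                 part, grad, fit$fit$message %||% "?"), call. = FALSE)
  }
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0) {
    warning(sprintf("fit_glmm: %s part optimizer reported '%s' (max |gradient| = %.3g); estimates returned, inspect before use",
                    part, fit$fit$message, grad), call. = FALSE)
  }
  est <- glmmTMB::fixef(fit)$cond
  if (anyNA(est)) {
    warning(sprintf("fit_glmm: %s part dropped rank-deficient term(s): %s",
                    part, paste(names(est)[is.na(est)], collapse = ", ")),
            call. = FALSE)
    est <- est[!is.na(est)]
  }
  vc <- vcov(fit)$cond
  se <- sqrt(diag(vc))[names(est)]
  z <- qnorm(1 - (1 - conf_level) / 2)
  pval <- 2 * pnorm(-abs(est / se))
  if (part == "occurrence" && any(abs(est) > 15 & se > 50)) {
    warning("fit_glmm: estimates suggest complete separation in the occurrence part; interpret with caution",
            call. = FALSE)
  }
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      exp_estimate = exp(unname(est)),
                      ci_low = exp(unname(est - z * se)),
                      ci_high = exp(unname(est + z * se)),
                      p = unname(pval), stringsAsFactors = FALSE)
  vc_re <- glmmTMB::VarCorr(fit)$cond
  ranef_var <- if (length(vc_re)) as.numeric(vc_re[[1]][1, 1]) else NA_real_
  out <- list(part = part, outcome = outcome, covariates = covariates,
              coefficients = coefs, n = nrow(data), ranef_var = ranef_var,
              logLik = as.numeric(logLik(fit)), model = fit)
  class(out) <- "pos_glmm"
  out
}

#' @export
print.pos_glmm <- function(x, ...) {
  cat(sprintf("%s part for %s (n = %d, school variance = %.3f)\n",
              x$part, x$outcome, x$n, x$ranef_var))
  tab <- x$coefficients
  tab$marker <- sig_marker(tab$p)
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

sig_marker <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ifelse(p < 0.1, "°", "")))
}

#' Fit a two-part multilevel hurdle model
#'
#' Pairs the logistic occurrence part (all rows, indicator
#' \code{outcome > 0}) with the gamma amount part (positive subset).
#' Degenerate cases are handled by contract: no zeros -> occurrence part
#' skipped with a notice; no positives -> amount part skipped. The joint
#' log-likelihood is the sum of the part log-likelihoods (the parts are
#' parameter-independent).
#'
#' @inheritParams fit_glmm
#' @param drop_occurrence covariates excluded from the occurrence part
#'   only (e.g. mean POS visits/day, which separates the occurrence
#'   indicator by construction)
#' @return object of class \code{pos_hurdle} with \code{$occurrence},
#'   \code{$amount} (either may be NULL), \code{$logLik}
#' @export
fit_hurdle <- function(data, outcome, covariates = character(),
                       group = "school_id", conf_level = 0.95,
                       drop_occurrence = character()) {
  y <- data[[outcome]]
  if (is.null(y)) stop_input("fit_hurdle: outcome %s not in data", outcome)
  occ <- NULL; amt <- NULL; notes <- character()
  if (any(y <= 0) && any(y > 0)) {
    occ <- fit_glmm(data, outcome, setdiff(covariates, drop_occurrence),
                    part = "occurrence",
                    group = group, conf_level = conf_level)
  } else {
    notes <- c(notes, if (all(y > 0))
      "no zeros: hurdle degenerate, occurrence part skipped"
      else "no positives: occurrence part skipped")
    message(notes[length(notes)])
  }
  if (any(y > 0)) {
    amt <- fit_glmm(data[y > 0, , drop = FALSE], outcome, covariates,
                    part = "amount", group = group, conf_level = conf_level)
  } else {
    notes <- c(notes, "no positive outcomes: amount part skipped")
    message(notes[length(notes)])
  }
  out <- list(outcome = outcome, occurrence = occ, amount = amt,
              notes = notes,
              logLik = sum(c(occ$logLik, amt$logLik)))
  class(out) <- "pos_hurdle"
  out
}

#' @export
print.pos_hurdle <- function(x, ...) {
  cat(sprintf("Multilevel hurdle model for %s\n", x$outcome))
  if (!is.null(x$occurrence)) print(x$occurrence)
  if (!is.null(x$amount)) print(x$amount)
  if (length(x$notes)) cat(paste0("note: ", x$notes, "\n"))
  invisible(x)
}

#' @export
logLik.pos_hurdle <- function(object, ...) object$logLik

#' Screen candidate covariates
#'
#' Enters all candidates simultaneously into one model on the outcome's
#' amount part (gamma, positive subset) and retains those with p <
#' \code{alpha}; \code{forced} covariates are always retained regardless
#' of their p-value. A factor is retained when any of its levels is
#' significant. Collinear candidates (model-matrix condition number above
#' \code{kappa_max}) trigger a warning.
#'
#' @param data model data
#' @param outcome outcome column
#' @param candidates character vector of candidate covariate names
#' @param forced covariates always retained
#' @param alpha significance level (default 0.05)
#' @param group random-intercept grouping column
#' @param kappa_max condition-number threshold for the collinearity
#'   warning
#' @return character vector of retained covariates (subset of candidates
#'   union forced)
#' @export
screen_covariates <- function(data, outcome, candidates, forced = character(),
                              alpha = 0.05, group = "school_id",
                              kappa_max = 1e4) {
  if (!length(candidates) && !length(forced)) return(character())
  pos <- data[data[[outcome]] > 0, , drop = FALSE]
  md <- prepare_model_data(pos)
  ## a candidate without variation on the positive subset cannot be related
  ## to anything and only degrades conditioning
  degenerate <- vapply(union(candidates, forced), function(cv) {
    length(unique(md[[cv]][!is.na(md[[cv]])])) < 2
  }, logical(1))
  if (any(degenerate)) {
    message("screen_covariates: dropping constant candidate(s): ",
            paste(names(degenerate)[degenerate], collapse = ", "))
    candidates <- setdiff(candidates, names(degenerate)[degenerate])
    forced <- setdiff(forced, names(degenerate)[degenerate])
    if (!length(candidates) && !length(forced)) return(character())
  }
  cand <- union(candidates, forced)
  mm <- stats::model.matrix(
    as.formula(paste("~", paste(cand, collapse = "+"))), data = md)
  ## scale columns so the condition number reflects collinearity, not units
  sds <- apply(mm[, -1, drop = FALSE], 2, sd)
  mm_s <- sweep(mm[, -1, drop = FALSE], 2, ifelse(sds > 0, sds, 1), "/")
  kap <- kappa(cbind(1, mm_s), exact = TRUE)
  if (!is.finite(kap) || kap > kappa_max) {
    cc <- suppressWarnings(stats::cor(mm[, -1, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)
    pair <- if (nrow(worst)) sprintf("; strongest pair: %s / %s",
                                     colnames(cc)[worst[1, 1]],
                                     colnames(cc)[worst[1, 2]]) else ""
    warning(sprintf("screen_covariates: collinear candidates (condition number %.3g)%s",
                    kap, pair), call. = FALSE)
  }
  fit <- fit_glmm(pos, outcome, cand, part = "amount", group = group)
  keep <- character()
  for (cv in candidates) {
    rows <- term_rows(fit$coefficients$term, cv, data)
    if (length(rows) && any(fit$coefficients$p[rows] < alpha, na.rm = TRUE)) {
      keep <- c(keep, cv)
    }
  }
  union(keep, forced)
}

## map a covariate name onto its coefficient rows (factor expansions)
term_rows <- function(terms, covariate, data) {
  col <- data[[covariate]]
  if (is.character(col) || is.factor(col)) {
    which(startsWith(terms, covariate) & terms != "(Intercept)")
  } else {
    which(terms == covariate)
  }
}
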