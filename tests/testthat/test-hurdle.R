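test_that("multilevel fits match single-level GLMs when school variance is zero", {
  d <- simulate_hurdle_data(n = 1500, beta_occ = c(gender_female = -0.4),
                            beta_amt = c(gender_female = -0.5),
                            school_sigma = 0, seed = 3)
  md <- prepare_model_data(d)
  occ <- fit_glmm(d, "pos_min_day", "gender", part = "occurrence")
  ref <- glm(I(pos_min_day > 0) ~ gender, data = md, family = binomial)
  expect_equal(occ$coefficients$estimate, unname(coef(ref)), tolerance = 1e-3)

  pos <- d[d$pos_min_day > 0, ]
  amt <- fit_glmm(pos, "pos_min_day", "gender", part = "amount")
  refg <- glm(pos_min_day ~ gender, data = prepare_model_data(pos),
              family = Gamma(link = "log"))
  expect_equal(amt$coefficients$estimate, unname(coef(refg)),
               tolerance = 1e-3)
})

test_that("hurdle bookkeeping: occurrence on all, amount on the positive subset", {
  d <- simulate_hurdle_data(n = 400, p0 = 0.75, seed = 5)
  h <- fit_hurdle(d, "pos_min_day", "gender")
  expect_equal(h$occurrence$n, 400)
  expect_equal(h$amount$n, sum(d$pos_min_day > 0))
  expect_gte(h$occurrence$n, h$amount$n)
  ## joint log-likelihood = sum of parts
  expect_equal(logLik(h), h$occurrence$logLik + h$amount$logLik)
  ## CI bounds bracket the exponentiated estimate
  for (part in list(h$occurrence, h$amount)) {
    expect_true(all(part$coefficients$ci_low <= part$coefficients$exp_estimate))
    expect_true(all(part$coefficients$ci_high >= part$coefficients$exp_estimate))
  }

  ## degenerate: all users -> occurrence skipped, amount on all
  d2 <- d; d2$pos_min_day <- d2$pos_min_day + 1
  expect_message(h2 <- fit_hurdle(d2, "pos_min_day", "gender"),
                 "occurrence part skipped")
  expect_null(h2$occurrence)
  expect_equal(h2$amount$n, 400)

  ## amount part refuses zeros outright
  expect_error(fit_glmm(d, "pos_min_day", "gender", part = "amount"),
               "strictly positive")
})

test_that("gamma amount part is scale-equivariant", {
  d <- simulate_hurdle_data(n = 800, beta_amt = c(gender_female = -0.5),
                            seed = 7)
  pos <- d[d$pos_min_day > 0, ]
  f1 <- fit_glmm(pos, "pos_min_day", "gender", part = "amount")
  pos$pos_min_day <- pos$pos_min_day * 3
  f2 <- fit_glmm(pos, "pos_min_day", "gender", part = "amount")
  expect_equal(f2$coefficients$estimate[1] - f1$coefficients$estimate[1],
               log(3), tolerance = 1e-5)
  expect_equal(f2$coefficients$estimate[-1], f1$coefficients$estimate[-1],
               tolerance = 1e-5)
})

test_that("exponentiation preserves coefficient ordering", {
  d <- simulate_hurdle_data(n = 600, beta_occ = c(gender_female = -0.4,
                                                  ses_low = 0.5),
                            seed = 11)
  occ <- fit_glmm(d, "pos_min_day", c("gender", "ses"), part = "occurrence")
  est <- occ$coefficients$estimate
  expect_equal(order(est), order(occ$coefficients$exp_estimate))
})

test_that("covariate screening retains strong effects, drops noise, honours forcing", {
  set.seed(13)
  d <- simulate_hurdle_data(n = 1200, beta_amt = c(age_c = 0.3),
                            school_sigma = 0.2, seed = 13)
  d$noise <- rnorm(nrow(d))
  keep <- screen_covariates(d, "pos_min_day", c("age", "noise"))
  expect_true("age" %in% keep)
  keep2 <- screen_covariates(d, "pos_min_day", c("age", "noise"),
                             forced = "noise")
  expect_true(all(c("age", "noise") %in% keep2))
  expect_equal(screen_covariates(d, "pos_min_day", character()), character())
  ## collinearity warning for a duplicated covariate
  d$age_copy <- d$age + rnorm(nrow(d), 0, 1e-4)
  expect_warning(screen_covariates(d, "pos_min_day", c("age", "age_copy")),
                 "collinear")
})

test_that("stepwise procedure advances only significant factors and reports markers", {
  d <- simulate_hurdle_data(
    n = 1200, beta_occ = c(gender_female = -1.2),
    beta_amt = c(gender_female = -0.8), school_sigma = 0.2, seed = 17)
  set.seed(18)
  d$n_days <- sample(1:2, nrow(d), replace = TRUE)
  d$wear_min_day <- rnorm(nrow(d), 700, 30)
  d$pos_visits_day <- ifelse(d$used_pos, 1, 0)
  d$visits_siblings <- rpois(nrow(d), 0.3)
  sw <- stepwise_procedure(
    d, "pos_min_day",
    individual_factors = c("gender", "sport_club"),
    social_factors = "visits_siblings",
    covariate_candidates = c("wear_min_day", "n_days"))
  expect_true("gender" %in% sw$selected_factors)
  expect_false("sport_club" %in% sw$selected_factors)
  expect_true(all(c("step2", "step3", "step4") %in% sw$table$step))
  expect_true(all(sw$table$marker[sw$table$p < 0.01] == "**"))
  gender_row <- sw$table[sw$table$step == "step2" &
                           sw$table$term == "genderfemale" &
                           sw$table$part == "occurrence", ]
  expect_lt(gender_row$exp_estimate[1], 1)
})
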