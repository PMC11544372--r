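make_cohort_data <- function(family_id, effects, n_families = 20,
                             phrases = 4, tokens = 2) {
  coh <- generate_cohort(tiny_plan(n_families = n_families, phrases = phrases,
                                   tokens = tokens),
                         vowel_inventory(), effects)
  spec <- model_spec(family_id)
  m <- suppressMessages(summarize_sessions(coh$tokens, coh$phrases))
  d <- suppressMessages(prepare_covariates(
    switch(spec$level, phrases = m$phrases, tokens = coh$tokens,
           sessions = m$sessions, variability = m$variability),
    spec))
  list(spec = spec, data = d, cohort = coh)
}

test_that("covariates are z-scored on the analysis sample", {
  x <- make_cohort_data(1, effect_config(seed = 31))
  expect_equal(mean(x$data$age_z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(x$data$age_z), 1, tolerance = 1e-12)
  expect_equal(mean(x$data$onset_z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(x$data$onset_z), 1, tolerance = 1e-12)
  expect_equal(attr(x$data, "age_center") +
                 attr(x$data, "age_scale") * x$data$age_z,
               x$data$child_age_days, tolerance = 1e-9)
  expect_equal(levels(x$data$register), c("ADS", "IDS"))
  expect_equal(levels(x$data$parent_gender), c("father", "mother"))
  # constant covariate is an error naming the column
  flat <- x$data
  flat$child_age_days <- 100
  expect_error(prepare_covariates(flat, x$spec), "child_age_days")
})

test_that("durations are rounded to 10 ms before the log transform", {
  expect_equal(log_round10(127), log(130))
  expect_equal(log_round10(124.9), log(120))
  expect_equal(log_round10(c(95, 104.9)), log(c(100, 100)))
  expect_error(log_round10(2), "positive")
})

test_that("the null specification removes register and all its interactions", {
  spec <- model_spec(1)
  nt <- null_model_terms(spec)
  dropped <- setdiff(spec$fixed, nt)
  expect_setequal(dropped, c("register", "register:age_z",
                             "register:parent_gender",
                             "register:age_z:parent_gender",
                             "onset_z:register"))
  expect_false(any(grepl("register", nt)))
  spec5 <- model_spec(5)
  expect_length(setdiff(spec5$fixed, null_model_terms(spec5)), 4L)
})

test_that("full-null comparison is a chi-square LRT with correct df", {
  x <- make_cohort_data(1, effect_config(pitch_shift_ids = 2, seed = 32))
  full <- fit_model(x$data, x$spec)
  null <- fit_model(x$data, x$spec, null_model_terms(x$spec))
  cmp <- full_null_comparison(full, null)
  expect_equal(cmp$df, length(setdiff(x$spec$fixed, null$terms)))
  expect_gte(cmp$statistic, 0)
  expect_lt(cmp$p_value, 0.01)
  # identical models: statistic 0, p 1
  self <- full_null_comparison(
    list(logLik = null$logLik, df = null$df + 1, converged = TRUE),
    null)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # non-nested order is an error
  expect_error(full_null_comparison(null, full), "nested")
})

test_that("an injected pitch shift is recovered by the pitch model", {
  x <- make_cohort_data(1, effect_config(pitch_shift_ids = 2.5, seed = 33),
                        n_families = 40, phrases = 5)
  full <- fit_model(x$data, x$spec)
  est <- full$estimates[full$estimates$term == "registerIDS", ]
  expect_lt(abs(est$estimate - 2.5), 3 * est$se + 0.25)
})

test_that("under a pure main effect all interactions are pruned", {
  x <- make_cohort_data(1, effect_config(pitch_shift_ids = 3, seed = 34),
                        n_families = 30, phrases = 4)
  pr <- prune_interactions(x$data, x$spec, alpha = 0.1)
  # the three-way interaction is tested first (highest order)
  expect_equal(pr$trace$order[1], 3L)
  expect_true(pr$trace$removed[1])
  # main effects survive whatever happens to the interactions
  expect_true(all(c("register", "age_z", "parent_gender", "child_gender",
                    "recording_order", "onset_z") %in% pr$fit$terms))
  # pruning never increases the likelihood above the full fit
  full <- fit_model(x$data, x$spec)
  expect_lte(pr$fit$logLik, full$logLik + 1e-6)
  # alpha = 1 removes nothing
  pr_all <- prune_interactions(x$data, x$spec, alpha = 1)
  expect_setequal(pr_all$fit$terms, x$spec$fixed)
})

test_that("a strong register-by-age interaction is retained by pruning", {
  eff <- effect_config(age_slopes = c(pitch_ids = 1.5, pitch_ads = -1.5),
                       pitch_shift_ids = 2, seed = 35)
  x <- make_cohort_data(1, eff, n_families = 40, phrases = 5)
  pr <- prune_interactions(x$data, x$spec, alpha = 0.1)
  expect_true("register:age_z" %in% pr$fit$terms)
})

test_that("model families use their declared response scales", {
  eff <- effect_config(duration_log_shift_ids = 0.1,
                       variability_inflation_ids = 2, seed = 36)
  x4 <- make_cohort_data(4, eff, n_families = 25, tokens = 3)
  expect_equal(sort(unique(round(exp(x4$data$response)) %% 10)), 0)
  f4 <- fit_model(x4$data, x4$spec)
  est4 <- f4$estimates[f4$estimates$term == "registerIDS", ]
  expect_lt(abs(est4$estimate - 0.1), 4 * est4$se + 0.02)
  x7 <- make_cohort_data(7, eff, n_families = 25, tokens = 3)
  f7 <- fit_model(x7$data, x7$spec)
  est7 <- f7$estimates[f7$estimates$term == "registerIDS", ]
  expect_lt(abs(est7$estimate - log(4)), 4 * est7$se + 0.15)
  # beta family responses live strictly inside (0, 1)
  x8 <- make_cohort_data(8, eff, n_families = 25, tokens = 3)
  expect_true(all(x8$data$response > 0 & x8$data$response < 1))
  f8 <- fit_model(x8$data, x8$spec)
  expect_true("registerIDS" %in% f8$estimates$term)
  # inflated within-category spread lowers distinctiveness in IDS
  expect_lt(f8$estimates$estimate[f8$estimates$term == "registerIDS"], 0)
})

test_that("bootstrap intervals are seeded and reproducible", {
  x <- make_cohort_data(5, effect_config(peripheralization_ids = 1.3,
                                         seed = 37),
                        n_families = 15, tokens = 2)
  fit <- fit_model(x$data, x$spec)
  ci1 <- suppressWarnings(bootstrap_ci(fit, n = 12, seed = 5))
  ci2 <- suppressWarnings(bootstrap_ci(fit, n = 12, seed = 5))
  expect_equal(ci1$lower, ci2$lower)
  expect_equal(ci1$upper, ci2$upper)
  expect_true(all(ci1$lower <= ci1$upper))
  expect_error(bootstrap_ci(fit, n = 0), "positive integer")
})

test_that("leave-one-out stability needs 3+ levels and brackets the estimate", {
  x <- make_cohort_data(5, effect_config(seed = 38), n_families = 10,
                        tokens = 2)
  st <- stability_leave_one_out(x$data, x$spec, "family_id")
  expect_true(all(st$min <= st$estimate + 1e-9))
  expect_true(all(st$max >= st$estimate - 1e-9))
  two <- x$data[x$data$family_id %in% c("F1", "F2"), ]
  expect_error(stability_leave_one_out(two, x$spec, "family_id"),
               "fewer than 3")
})
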