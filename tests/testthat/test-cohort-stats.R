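test_that("assumption checks leave normal data alone and log-transform skewed data", {
  set.seed(61)
  g <- rep(c("a", "b"), each = 50)
  v <- rnorm(100)
  r <- check_and_transform(v, g)
  expect_false(r$transform_applied)
  expect_identical(r$values, v)

  # log-normal data triggers the transform in >= 90% of replicates
  hits <- mean(replicate(100, {
    vl <- exp(rnorm(60, sd = 1))
    check_and_transform(vl, rep(c("a", "b"), each = 30))$transform_applied
  }))
  expect_gte(hits, 0.9)

  # non-positive values are shifted before the log
  vneg <- c(exp(rnorm(30, sd = 1.5)) - 2, exp(rnorm(30, sd = 1.5)))
  rn <- check_and_transform(vneg, rep(c("a", "b"), each = 30))
  if (rn$transform_applied) {
    expect_true(all(is.finite(rn$values)))
    expect_gt(rn$shift, 0)
  }

  # constant input is flagged degenerate, not an error
  rc <- check_and_transform(rep(2, 20), rep(c("a", "b"), each = 10))
  expect_true(rc$degenerate)
  expect_false(rc$transform_applied)

  expect_error(check_and_transform(1:4, c("a", "a", "b", "b")), "fewer than 3")
})

test_that("the group/ROI ANCOVA matches a from-scratch nested-model F oracle", {
  set.seed(62)
  ot <- simulated_outcomes(cohort_spec(seed = 63, effect_scale = 1))
  res <- ancova_group_roi(ot, "iba1_od", m = 1, transform = FALSE)
  expect_s3_class(res, "glia_tests")
  expect_setequal(res$effect, c("group", "roi"))

  # oracle: partial F by explicit residual-sum-of-squares arithmetic
  d <- ot[ot$outcome_name == "iba1_od", ]
  full <- lm(value ~ group + roi_name + age + sex + fixation_interval_months,
             data = d)
  f_oracle <- function(drop_term) {
    red <- update(full, paste(". ~ . -", drop_term))
    rss_f <- sum(resid(full)^2); rss_r <- sum(resid(red)^2)
    q <- full$rank - red$rank
    ((rss_r - rss_f) / q) / (rss_f / df.residual(full))
  }
  expect_equal(res$statistic[res$effect == "group"], f_oracle("group"),
               tolerance = 1e-6)
  expect_equal(res$statistic[res$effect == "roi"], f_oracle("roi_name"),
               tolerance = 1e-6)
  expect_equal(res$df2[1], df.residual(full))
})

test_that("ANCOVA group p agrees with a Freedman-Lane permutation oracle", {
  set.seed(64)
  ot <- simulated_outcomes(cohort_spec(seed = 65, effect_scale = 0.4))
  d <- ot[ot$outcome_name == "iba1_od", ]
  res <- ancova_group_roi(ot, "iba1_od", m = 1, transform = FALSE)
  f_obs <- res$statistic[res$effect == "group"]

  X_red <- model.matrix(~ roi_name + age + sex + fixation_interval_months,
                        data = d)
  X_full <- model.matrix(~ group + roi_name + age + sex +
                           fixation_interval_months, data = d)
  fit_red <- lm.fit(X_red, d$value)
  fitted_red <- fit_red$fitted.values
  res_red <- fit_red$residuals
  q <- qr(X_full)
  n <- nrow(d); p_full <- ncol(X_full); p_red <- ncol(X_red)
  f_perm <- replicate(10000, {
    y_star <- fitted_red + sample(res_red)
    rss_f <- sum(qr.resid(q, y_star)^2)
    rss_r <- sum(lm.fit(X_red, y_star)$residuals^2)
    ((rss_r - rss_f) / (p_full - p_red)) / (rss_f / (n - p_full))
  })
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_perm - res$p_raw[res$effect == "group"]), 0.03)
})

test_that("F statistics are invariant to rescaling the outcome", {
  set.seed(66)
  ot <- simulated_outcomes(cohort_spec(seed = 67))
  r1 <- ancova_group_roi(ot, "gfap_od", m = 1, transform = FALSE)
  ot2 <- ot
  ot2$value[ot2$outcome_name == "gfap_od"] <-
    ot2$value[ot2$outcome_name == "gfap_od"] * 1000
  r2 <- ancova_group_roi(ot2, "gfap_od", m = 1, transform = FALSE)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
})

test_that("Bonferroni correction is min(1, m p) and family sizes match blocks", {
  expect_equal(bonferroni_family_size("iba1_intensity_pct"), 5L)
  expect_equal(bonferroni_family_size("gfap_area_pct"), 2L)
  expect_equal(bonferroni_family_size("pct_severe"), 5L)
  expect_equal(bonferroni_family_size("something_else"), 1L)
  set.seed(68)
  ot <- simulated_outcomes(cohort_spec(seed = 69))
  r <- ancova_group_roi(ot, "iba1_od", m = 7, transform = FALSE)
  expect_equal(r$p_bonferroni, pmin(1, 7 * r$p_raw))
  expect_true(all(r$p_bonferroni >= r$p_raw))
})

test_that("rank-deficient designs drop the offending covariate with a warning", {
  set.seed(70)
  ot <- simulated_outcomes(cohort_spec(seed = 71))
  ot$sex <- "F"   # single-sex cohort: sex is constant
  expect_warning(r <- ancova_group_roi(ot, "iba1_od", m = 1,
                                       transform = FALSE),
                 "constant covariate")
  expect_true(all(is.finite(r$statistic)))
})

test_that("chi-square tests are Pearson without continuity correction", {
  r0 <- chi_square_test(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  # hand-computable: expected 12.5 everywhere, sum((o-e)^2/e) = 18
  r <- chi_square_test(matrix(c(20, 5, 5, 20), 2))
  expect_equal(r$statistic, 18)
  expect_equal(r$df1, 1)
  expect_error(chi_square_test(matrix(c(3, 7), 1)), "2 x 2")
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("burden stratification splits Fazekas 0-1 from 2-3", {
  subj <- data.frame(subject_id = paste0("S", 1:4), fazekas = c(0, 1, 2, 3))
  s <- stratify_burden(subj)
  expect_equal(as.character(s), c("mild", "mild", "moderate_severe",
                                  "moderate_severe"))
  expect_error(stratify_burden(data.frame(subject_id = "a", fazekas = 4)),
               "0-3")
})

test_that("burden analysis detects a burden-linked effect and rejects empty strata", {
  set.seed(72)
  spec <- cohort_spec(seed = 73, effect_scale = 0, burden_iba1_od = 0.15)
  ot <- simulated_outcomes(spec)
  r <- burden_analysis(ot, "iba1_od", m = 1, transform = FALSE)
  expect_lt(r$p_raw[r$effect == "burden"], 0.05)

  ot$fazekas <- 0
  expect_error(burden_analysis(ot, "iba1_od"), "stratum")
})

test_that("null burden rejection stays near alpha", {
  set.seed(74)
  rej <- mean(replicate(120, {
    ot <- simulated_outcomes(cohort_spec(seed = sample.int(1e7, 1),
                                         effect_scale = 0))
    r <- burden_analysis(ot, "gfap_od", m = 1, transform = FALSE)
    r$p_raw[r$effect == "burden"] < 0.05
  }))
  expect_lt(rej, 0.12)
})

test_that("demographics tables match hand computation and report available n", {
  subj <- data.frame(
    subject_id = paste0("S", 1:6),
    group = c(rep("hypertension", 3), rep("control", 3)),
    age = c(70, 80, 90, 72, 78, 84),
    sex = c("F", "M", "F", "M", "M", "F"),
    fixation_interval_months = c(30, 40, 50, 35, 45, 55),
    fazekas = c(2, 1, 3, 0, 1, 1),
    bmi = c(22, 25, NA, 24, NA, 26))
  d <- demographics_table(subj)
  age_row <- d[d$variable == "age", ]
  expect_equal(age_row$hypertension, sprintf("%.1f ± %.1f", 80, 10))
  expect_equal(age_row$control, sprintf("%.1f ± %.1f", 78, 6))
  bmi_row <- d[d$variable == "bmi", ]
  expect_equal(bmi_row$n_available, 4L)   # two missing BMI values dropped
  sex_row <- d[grepl("sex", d$variable), ]
  expect_equal(sex_row$n_available, 6L)
  expect_true(all(is.na(d$p_value) | (d$p_value >= 0 & d$p_value <= 1)))

  # identical groups: chi-square p = 1 for the categorical rows
  subj2 <- subj
  subj2$group <- rep(c("hypertension", "control"), 3)
  subj2$age <- rep(c(70, 80, 90), 2)[order(rep(1:3, 2))]
  subj2 <- data.frame(subject_id = paste0("S", 1:6),
                      group = rep(c("hypertension", "control"), each = 3),
                      age = rep(c(70, 80, 90), 2),
                      sex = rep(c("F", "M", "F"), 2),
                      fixation_interval_months = rep(c(30, 40, 50), 2),
                      fazekas = rep(c(1, 2, 0), 2))
  d2 <- demographics_table(subj2)
  expect_equal(d2$p_value[grepl("sex", d2$variable)], 1)
  expect_gt(d2$p_value[d2$variable == "age"], 0.9)
  expect_error(demographics_table(subj[1, ]), "at least 2")
})

test_that("the mixed-model flag fits a subject random intercept", {
  set.seed(75)
  ot <- simulated_outcomes(cohort_spec(seed = 76, effect_scale = 1))
  r <- ancova_group_roi(ot, "iba1_od", m = 1, transform = FALSE,
                        mixed = TRUE)
  expect_s3_class(r, "glia_tests")
  expect_setequal(r$effect, c("group", "roi"))
  expect_true(all(is.finite(r$statistic)))
  expect_true(all(r$p_raw >= 0 & r$p_raw <= 1))
  # both parameterisations detect the simulated group and ROI effects
  rf <- ancova_group_roi(ot, "iba1_od", m = 1, transform = FALSE)
  expect_lt(r$p_raw[r$effect == "group"], 0.05)
  expect_lt(rf$p_raw[rf$effect == "group"], 0.05)
  expect_lt(r$p_raw[r$effect == "roi"], 0.05)
  # the mixed fit uses fewer denominator df for the between-subject effect
  expect_lte(r$df2[r$effect == "group"], rf$df2[rf$effect == "group"])
})

test_that("demographics accepts a WMH volume vector", {
  subj <- data.frame(subject_id = paste0("S", 1:6),
                     group = rep(c("hypertension", "control"), each = 3),
                     age = c(70, 80, 90, 72, 78, 84),
                     sex = rep(c("F", "M"), 3),
                     fixation_interval_months = seq(30, 55, by = 5),
                     fazekas = c(2, 1, 3, 0, 1, 1))
  vols <- setNames(c(2.1, 1.8, 2.6, 0.9, 1.1, 1.0), subj$subject_id)
  d <- demographics_table(subj, wmh_volumes = vols)
  row <- d[d$variable == "wmh_volume_ml", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$hypertension,
               sprintf("%.1f ± %.1f", mean(c(2.1, 1.8, 2.6)),
                       sd(c(2.1, 1.8, 2.6))))
})
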