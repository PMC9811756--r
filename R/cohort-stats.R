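# Cohort-level statistics: assumption checks with natural-log fallback,
# covariate-adjusted two-factor ANOVA (group x ROI, controlled for age, sex
# and fixation interval) with Bonferroni correction, chi-square tests for
# categorical variables, and WMH-burden stratification (Fazekas 0-1 vs 2-3).

# Bonferroni family sizes: one family per outcome block of the report
# (microglia: 5 outcomes; astroglia: 2; perivascular: 5).
BONFERRONI_FAMILIES <- list(
  microglia = c("iba1_frequency_per_mm2", "iba1_area_pct", "iba1_intensity_pct",
                "iba1_avg_length_um", "iba1_avg_circularity"),
  astroglia = c("gfap_area_pct", "gfap_intensity_pct"),
  perivascular = c("pct_with_inflammation", "pct_mild", "pct_moderate",
                   "pct_severe", "pct_close_range")
)

#' Bonferroni family size of an outcome
#' @param outcome_name outcome column name.
#' @return integer family size m (1 when the outcome is in no known family).
#' @export
bonferroni_family_size <- function(outcome_name) {
  for (fam in BONFERRONI_FAMILIES)
    if (outcome_name %in% fam) return(length(fam))
  1L
}

#' Normality / homogeneity check with natural-log fallback
#'
#' Shapiro-Wilk per group and Levene's test (mean-centred) at `alpha`; when
#' either fails, values are natural-log transformed (shifted by
#' `-min + epsilon` first when non-positive values are present).
#'
#' @param values numeric outcome vector.
#' @param groups grouping factor (>= 3 values per group required).
#' @param alpha significance level of the assumption checks.
#' @param epsilon shift offset for non-positive values.
#' @return list: `values`, `transform_applied`, `shift`, `degenerate`
#'   (constant input, returned unchanged).
#' @export
check_and_transform <- function(values, groups, alpha = 0.05,
                                epsilon = 1e-6) {
  groups <- droplevels(as.factor(groups))
  ok <- is.finite(values)
  if (any(table(groups[ok]) < 3)) stop("fewer than 3 values per group")
  v <- values[ok]
  if (stats::sd(v) == 0)
    return(list(values = values, transform_applied = FALSE, shift = 0,
                degenerate = TRUE))
  normal_ok <- all(vapply(split(v, groups[ok]), function(g) {
    if (stats::sd(g) == 0 || length(g) < 3) return(TRUE)
    stats::shapiro.test(g)$p.value > alpha
  }, logical(1)))
  lev <- car::leveneTest(v ~ groups[ok], center = mean)
  homo_ok <- lev[["Pr(>F)"]][1] > alpha
  if (normal_ok && homo_ok)
    return(list(values = values, transform_applied = FALSE, shift = 0,
                degenerate = FALSE))
  shift <- if (min(v) <= 0) -min(v) + epsilon else 0
  out <- values
  out[ok] <- log(v + shift)
  list(values = out, transform_applied = TRUE, shift = shift,
       degenerate = FALSE)
}

test_result <- function(outcome_name, effect, statistic, df1, df2, p_raw, m,
                        transform_applied, n_used) {
  data.frame(outcome_name = outcome_name, effect = effect,
             statistic = statistic, df1 = df1, df2 = df2,
             p_raw = p_raw, p_bonferroni = pmin(1, m * p_raw),
             m = m, transform_applied = transform_applied, n_used = n_used,
             stringsAsFactors = FALSE)
}

# Shared workhorse: covariate-adjusted linear model with Type-III F tests
# for the factor(s) of interest.
ancova_fit <- function(df, outcome_name, factor_name,
                       covariates = c("age", "sex", "fixation_interval_months"),
                       include_roi = TRUE, m = NULL, transform = TRUE) {
  df <- df[is.finite(df$value), , drop = FALSE]
  df[[factor_name]] <- droplevels(as.factor(df[[factor_name]]))
  if (include_roi) df$roi_name <- droplevels(as.factor(df$roi_name))
  # drop covariates that are constant or absent (rank-deficient design)
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(df)) next
    x <- df[[cv]]
    if (length(unique(x[is.finite(as.numeric(as.factor(x)))])) < 2) {
      warning("dropping constant covariate: ", cv)
      next
    }
    keep <- c(keep, cv)
  }
  tr <- if (transform) check_and_transform(df$value, df[[factor_name]])
        else list(values = df$value, transform_applied = FALSE)
  df$value <- tr$values
  terms <- c(factor_name, if (include_roi) "roi_name", keep)
  fml <- stats::reformulate(terms, response = "value")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    # aliased columns: retry without the offending covariates
    al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    drop_cv <- keep[vapply(keep, function(k) any(grepl(k, al, fixed = TRUE)),
                           logical(1))]
    if (length(drop_cv)) {
      warning("dropping aliased covariate(s): ",
              paste(drop_cv, collapse = ", "))
      keep <- setdiff(keep, drop_cv)
      fml <- stats::reformulate(c(factor_name, if (include_roi) "roi_name",
                                  keep), response = "value")
      fit <- stats::lm(fml, data = df)
    }
  }
  aov3 <- car::Anova(fit, type = "III")
  if (is.null(m)) m <- bonferroni_family_size(outcome_name)
  eff_rows <- c(factor_name, if (include_roi) "roi_name")
  eff_names <- c(if (factor_name == "group") "group" else "burden",
                 if (include_roi) "roi")
  res <- list()
  for (i in seq_along(eff_rows)) {
    r <- aov3[eff_rows[i], ]
    res[[i]] <- test_result(outcome_name, eff_names[i], r[["F value"]],
                            r[["Df"]], aov3["Residuals", "Df"],
                            r[["Pr(>F)"]], m, tr$transform_applied, nrow(df))
  }
  structure(do.call(rbind, res), class = c("glia_tests", "data.frame"),
            fit = fit)
}

#' Group x ROI ANCOVA for one outcome
#'
#' Linear model `value ~ group + roi + age + sex + fixation interval` with
#' Type-III F tests for the group and ROI effects, after the assumption
#' check / log-transform of [check_and_transform()]. Bonferroni m defaults
#' to the size of the outcome's family block (see
#' [bonferroni_family_size()]).
#'
#' @param outcome_table long data.frame with columns `subject_id`,
#'   `roi_name`, `outcome_name`, `value`, joined to the covariates `group`,
#'   `age`, `sex`, `fixation_interval_months`.
#' @param outcome_name which outcome to test.
#' @param covariates covariate columns to adjust for.
#' @param m Bonferroni family size override.
#' @param transform run the assumption check / log fallback.
#' @param mixed add a per-subject random intercept (fitted with `lmerTest`,
#'   Satterthwaite F tests). The default is the ordinary linear model with
#'   ROI as a fixed crossed factor, mirroring the covariate-adjusted ANOVA
#'   this pipeline reproduces.
#' @return data.frame of class `glia_tests` (one row per effect).
#' @export
ancova_group_roi <- function(outcome_table, outcome_name,
                             covariates = c("age", "sex",
                                            "fixation_interval_months"),
                             m = NULL, transform = TRUE, mixed = FALSE) {
  df <- outcome_table[outcome_table$outcome_name == outcome_name, ,
                      drop = FALSE]
  if (nrow(df) == 0) stop("unknown outcome: ", outcome_name)
  if (length(unique(df$group)) < 2 || length(unique(df$roi_name)) < 2)
    stop("both groups and both ROIs must be represented")
  if (mixed)
    return(ancova_mixed(df, outcome_name, "group", covariates, m, transform))
  ancova_fit(df, outcome_name, "group", covariates, include_roi = TRUE,
             m = m, transform = transform)
}

# Mixed-model alternative: per-subject random intercept, Satterthwaite
# Type-III F tests via lmerTest.
ancova_mixed <- function(df, outcome_name, factor_name, covariates,
                         m = NULL, transform = TRUE) {
  df <- df[is.finite(df$value), , drop = FALSE]
  df[[factor_name]] <- droplevels(as.factor(df[[factor_name]]))
  df$roi_name <- droplevels(as.factor(df$roi_name))
  keep <- covariates[vapply(covariates, function(cv)
    cv %in% names(df) && length(unique(df[[cv]])) > 1, logical(1))]
  tr <- if (transform) check_and_transform(df$value, df[[factor_name]])
        else list(values = df$value, transform_applied = FALSE)
  df$value <- tr$values
  fml <- stats::as.formula(paste("value ~", factor_name, "+ roi_name",
                                 if (length(keep))
                                   paste("+", paste(keep, collapse = " + "))
                                 else "",
                                 "+ (1 | subject_id)"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- lmerTest::lmer(fml, data = df)
  aov3 <- stats::anova(fit, type = "III")
  if (is.null(m)) m <- bonferroni_family_size(outcome_name)
  eff_names <- c(if (factor_name == "group") "group" else "burden", "roi")
  res <- lapply(seq_along(c(factor_name, "roi_name")), function(i) {
    r <- aov3[c(factor_name, "roi_name")[i], ]
    test_result(outcome_name, eff_names[i], r[["F value"]], r[["NumDF"]],
                r[["DenDF"]], r[["Pr(>F)"]], m, tr$transform_applied,
                nrow(df))
  })
  structure(do.call(rbind, res), class = c("glia_tests", "data.frame"),
            fit = fit)
}

#' @export
print.glia_tests <- function(x, ...) {
  cat("Covariate-adjusted ANOVA (Type III), Bonferroni-corrected\n")
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_bonferroni <- signif(df$p_bonferroni, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test for a contingency table
#'
#' Without continuity correction.
#'
#' @param tab matrix of non-negative integer counts (r x c, both >= 2).
#' @param outcome_name label for the result row.
#' @param m Bonferroni family size (default 1).
#' @return one-row `glia_tests` data.frame (statistic = chi-square).
#' @export
chi_square_test <- function(tab, outcome_name = NA_character_, m = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(test_result(outcome_name, "association",
                        unname(ct$statistic), unname(ct$parameter), NA_real_,
                        ct$p.value, m, FALSE, sum(tab)),
            class = c("glia_tests", "data.frame"))
}

#' Stratify subjects by WMH burden
#'
#' Fazekas 0-1 = mild; 2-3 = moderate to severe.
#'
#' @param subjects cohort table with a `fazekas` column.
#' @return factor (levels `mild`, `moderate_severe`) named by subject id.
#' @export
stratify_burden <- function(subjects) {
  if (any(!subjects$fazekas %in% 0:3)) stop("fazekas outside 0-3")
  out <- factor(ifelse(subjects$fazekas <= 1, "mild", "moderate_severe"),
                levels = c("mild", "moderate_severe"))
  names(out) <- subjects$subject_id
  out
}

#' WMH-burden ANCOVA for one outcome
#'
#' Same covariate-adjusted model as [ancova_group_roi()] with the burden
#' stratum (mild vs moderate-severe) replacing group.
#'
#' @inheritParams ancova_group_roi
#' @export
burden_analysis <- function(outcome_table, outcome_name,
                            covariates = c("age", "sex",
                                           "fixation_interval_months"),
                            m = NULL, transform = TRUE) {
  df <- outcome_table[outcome_table$outcome_name == outcome_name, ,
                      drop = FALSE]
  if (nrow(df) == 0) stop("unknown outcome: ", outcome_name)
  if (!"burden" %in% names(df)) {
    if (!"fazekas" %in% names(df)) stop("need a fazekas or burden column")
    df$burden <- ifelse(df$fazekas <= 1, "mild", "moderate_severe")
  }
  if (length(unique(df$burden)) < 2) stop("empty burden stratum")
  ancova_fit(df, outcome_name, "burden", covariates, include_roi = TRUE,
             m = m, transform = transform)
}

#' Demographics summary table
#'
#' Per-variable group comparison: mean +/- SD and one-way ANOVA p for
#' continuous variables; n (percent) and Pearson chi-square p for
#' categorical/logical variables. Missing values are dropped per row and the
#' available n reported.
#'
#' @param subjects cohort table ([read_cohort_table()]); extra columns are
#'   summarised too.
#' @param wmh_volumes optional named numeric vector (subject id -> WMH
#'   volume in mL), added as a `wmh_volume_ml` row.
#' @param continuous,categorical variable names; defaults cover the standard
#'   columns plus any extra numeric / logical columns.
#' @return data.frame of class `demographics_table`.
#' @export
demographics_table <- function(subjects, wmh_volumes = NULL,
                               continuous = NULL, categorical = NULL) {
  if (nrow(subjects) < 2) stop("need at least 2 subjects")
  if (!is.null(wmh_volumes))
    subjects$wmh_volume_ml <- unname(wmh_volumes[subjects$subject_id])
  std_cont <- intersect(c("age", "fixation_interval_months", "wmh_volume_ml",
                          "bmi", "post_mortem_delay_h"), names(subjects))
  std_cat <- intersect(c("sex", "diabetes", "hypercholesterolemia",
                         "smoking", "alcohol"), names(subjects))
  if (is.null(continuous)) continuous <- std_cont
  if (is.null(categorical)) categorical <- std_cat
  g <- factor(subjects$group, levels = c("control", "hypertension"))
  rows <- list()
  for (v in continuous) {
    x <- as.numeric(subjects[[v]])
    ok <- is.finite(x)
    p <- if (length(unique(g[ok])) > 1 && stats::sd(x[ok]) > 0)
      summary(stats::aov(x[ok] ~ g[ok]))[[1]][["Pr(>F)"]][1] else NA_real_
    fmt <- function(sel) sprintf("%.1f ± %.1f", mean(x[sel & ok]),
                                 stats::sd(x[sel & ok]))
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      total = fmt(rep(TRUE, length(x))),
      control = fmt(g == "control"),
      hypertension = fmt(g == "hypertension"),
      n_available = sum(ok), p_value = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- subjects[[v]]
    ok <- !is.na(x)
    lv <- if (is.logical(x)) TRUE else sort(unique(x[ok]))[1]
    hit <- x == lv & ok
    tab <- table(factor(g[ok]), factor(x[ok]))
    p <- if (nrow(tab) >= 2 && ncol(tab) >= 2 &&
             all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      else NA_real_
    fmt <- function(sel) {
      n <- sum(hit & sel)
      sprintf("%d (%.1f%%)", n, 100 * n / max(1, sum(sel & ok)))
    }
    rows[[v]] <- data.frame(
      variable = paste0(v, " = ", lv), type = "categorical",
      total = fmt(rep(TRUE, length(x))),
      control = fmt(g == "control"),
      hypertension = fmt(g == "hypertension"),
      n_available = sum(ok), p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("demographics_table", "data.frame")
  out
}

#' Run the full statistical battery over an outcome table
#'
#' Group x ROI ANCOVA for every outcome present, plus the burden analysis.
#'
#' @param outcome_table long outcome table (see [ancova_group_roi()]).
#' @param covariates covariates to adjust for.
#' @param mixed use the random-intercept model for the group analysis.
#' @return `glia_tests` data.frame with all effects.
#' @export
run_cohort_stats <- function(outcome_table,
                             covariates = c("age", "sex",
                                            "fixation_interval_months"),
                             mixed = FALSE) {
  outs <- unique(outcome_table$outcome_name)
  res <- list()
  for (o in outs) {
    res[[paste0(o, "_group")]] <- tryCatch(
      ancova_group_roi(outcome_table, o, covariates, mixed = mixed),
      error = function(e) NULL)
    res[[paste0(o, "_burden")]] <- tryCatch(
      burden_analysis(outcome_table, o, covariates),
      error = function(e) NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("glia_tests", "data.frame")
  out
}
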