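# Group-comparison statistics: Shapiro-Wilk and Levene screens, Welch t,
# Pearson chi-square, Cohen's d, and the two standard report tables.

#' Shapiro-Wilk normality p-value
#'
#' @param x Numeric values, at least 3.
#' @return The Shapiro-Wilk p-value (reporting only; group tests always use
#'   Welch's t regardless of this screen).
#' @export
normality_p <- function(x) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 3, "Shapiro-Wilk needs at least 3 values")
  shapiro.test(x)$p.value
}

#' Levene variance-homogeneity p-value (median-centred)
#'
#' @param a,b Numeric samples, each with at least 3 values.
#' @return Levene test p-value (Brown-Forsythe variant, centre = median).
#' @export
variance_homogeneity_p <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  assert_that(length(a) >= 3 && length(b) >= 3,
              "Levene test needs at least 3 values per group")
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  car::leveneTest(y, g, center = median)[1, "Pr(>F)"]
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch statistic with Satterthwaite degrees of freedom, the
#' default comparison for continuous gait variables.
#'
#' @param a,b Numeric samples (at least 2 finite values each).
#' @return One-row tibble: `statistic` (t, a minus b), `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  assert_that(length(a) >= 2 && length(b) >= 2,
              "Welch t needs at least 2 values per group")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(tibble(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Expected counts from the margins; no continuity correction by default
#' (switchable), matching the usual convention at moderate counts.
#'
#' @param tab 2x2 (or larger) matrix of counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && sum(tab) > 0, "counts must be non-negative")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "chi-square undefined with an empty row or column")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Cohen's d (pooled SD)
#'
#' `(mean(a) - mean(b)) / s_p` with the pooled standard deviation
#' `s_p = sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))`; the sign of
#' the difference is kept.
#'
#' @param a,b Numeric samples (at least 2 finite values each).
#' @return Signed effect size.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  assert_that(na >= 2 && nb >= 2, "Cohen's d needs at least 2 values per group")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Compare one continuous parameter between two groups
#'
#' Means, SDs, Welch's t, Cohen's d, plus the Shapiro-Wilk and Levene
#' screening p-values (reported, never used to switch tests).
#'
#' @param a,b Numeric per-participant values.
#' @param parameter Parameter label.
#' @return One-row tibble (a `group_comparison` row).
#' @export
compare_groups <- function(a, b, parameter = "parameter") {
  w <- welch_t(a, b)
  tibble(
    parameter = parameter,
    mean_a = mean(a, na.rm = TRUE), sd_a = sd(a[is.finite(a)]),
    mean_b = mean(b, na.rm = TRUE), sd_b = sd(b[is.finite(b)]),
    test = "welch_t",
    statistic = w$statistic, df = w$df, p_value = w$p_value,
    cohens_d = cohens_d(a, b),
    normality_p_a = tryCatch(normality_p(a), error = function(e) NA_real_),
    normality_p_b = tryCatch(normality_p(b), error = function(e) NA_real_),
    levene_p = tryCatch(variance_homogeneity_p(a, b),
                        error = function(e) NA_real_)
  )
}

table1_rows <- c("Age (years)", "Sex (male/female)", "BMI (kg/m2)",
                 "Gait speed (m/s)", "Stride length (m)", "Step width (cm)",
                 "Cadence (steps/min)", "Double support (%cycle)",
                 "Step length asymmetry (%)")

#' Demographics and basic gait comparison table
#'
#' Builds the standard cohort-description table: demographics (age, sex,
#' BMI) followed by the six spatiotemporal parameters, in the conventional
#' row order and units (step width reported in cm). Continuous rows use
#' Welch's t; the sex row uses a Pearson chi-square on the male/female
#' counts.
#'
#' @param summary_a,summary_b Per-participant spatiotemporal tibbles (see
#'   [participant_summary()]), group A conventionally the control group.
#' @param demographics_a,demographics_b Optional tibbles with columns `age`,
#'   `sex` (`"M"`/`"F"`), `bmi`; demographic rows are skipped when absent.
#' @return Tibble, one row per parameter: group means/SDs (for sex, the
#'   male/female counts), `test`, `statistic`, `df`, `p_value`, `cohens_d`.
#' @export
build_table1 <- function(summary_a, summary_b,
                         demographics_a = NULL, demographics_b = NULL) {
  rows <- list()
  if (!is.null(demographics_a) && !is.null(demographics_b)) {
    rows$age <- compare_groups(demographics_a$age, demographics_b$age,
                               "Age (years)")
    counts <- rbind(a = table(factor(demographics_a$sex, c("M", "F"))),
                    b = table(factor(demographics_b$sex, c("M", "F"))))
    cs <- chi_square(counts)
    rows$sex <- tibble(
      parameter = "Sex (male/female)",
      mean_a = counts["a", "M"], sd_a = counts["a", "F"],
      mean_b = counts["b", "M"], sd_b = counts["b", "F"],
      test = "chi_square", statistic = cs$statistic, df = cs$df,
      p_value = cs$p_value, cohens_d = NA_real_,
      normality_p_a = NA_real_, normality_p_b = NA_real_,
      levene_p = NA_real_)
    rows$bmi <- compare_groups(demographics_a$bmi, demographics_b$bmi,
                               "BMI (kg/m2)")
  }
  gait <- list(
    c("gait_speed", "Gait speed (m/s)", 1),
    c("stride_length", "Stride length (m)", 1),
    c("step_width", "Step width (cm)", 100),
    c("cadence", "Cadence (steps/min)", 1),
    c("double_support_pct", "Double support (%cycle)", 1),
    c("step_length_asymmetry_pct", "Step length asymmetry (%)", 1)
  )
  for (g in gait) {
    scale <- as.numeric(g[3])
    rows[[g[1]]] <- compare_groups(summary_a[[g[1]]] * scale,
                                   summary_b[[g[1]]] * scale, g[2])
  }
  out <- bind_rows(rows)
  out$parameter <- factor(out$parameter, levels = table1_rows)
  out <- arrange(out, .data$parameter)
  out$parameter <- as.character(out$parameter)
  out
}

table2_rows <- tibble::tibble(
  joint = c("Pelvis", "Pelvis", "Pelvis",
            "Hip", "Hip", "Hip", "Hip", "Hip", "Hip",
            "Knee", "Knee", "Ankle", "Ankle", "Subtalar", "Subtalar"),
  dof = c("pelvis_tilt", "pelvis_list", "pelvis_rotation",
          rep("hip_flexion", 2), rep("hip_adduction", 2),
          rep("hip_rotation", 2), rep("knee_angle", 2),
          rep("ankle_angle", 2), rep("subtalar_angle", 2)),
  measure = c("peak", "peak", "peak",
              "flexion", "extension", "adduction", "abduction",
              "internal_rotation", "external_rotation",
              "flexion", "extension", "dorsiflexion", "plantarflexion",
              "inversion", "eversion")
)

#' Peak joint-angle comparison table
#'
#' Builds the standard 15-row peak-angle table: pelvis tilt/list/rotation,
#' hip flexion/extension/adduction/abduction/internal/external rotation,
#' knee flexion/extension, ankle dorsiflexion/plantarflexion and subtalar
#' inversion/eversion. Control values are the per-participant mean of the
#' left and right sides (the bilateral average); the experimental group
#' contributes its affected and unaffected sides, each compared with the
#' control bilateral average by Welch's t.
#'
#' @param peaks_control Per-participant peak tibble (see
#'   [participant_summary()]) for the control group.
#' @param peaks_exp Same for the experimental group.
#' @param affected Tibble mapping experimental `participant` to
#'   `affected_side` (`"L"`/`"R"`).
#' @return Tibble, one row per peak parameter: control/affected/unaffected
#'   means and SDs, and two p-values (`p_affected`, `p_unaffected`, each
#'   side vs. the control bilateral average) with matching Cohen's d.
#' @export
build_table2 <- function(peaks_control, peaks_exp, affected) {
  ctrl <- peaks_control %>%
    group_by(.data$participant, .data$dof, .data$measure) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ex <- peaks_exp %>%
    left_join(affected, by = "participant") %>%
    mutate(role = dplyr::if_else(.data$side == .data$affected_side,
                                 "affected", "unaffected"))
  purrr::map_dfr(seq_len(nrow(table2_rows)), function(i) {
    d <- table2_rows$dof[i]; m <- table2_rows$measure[i]
    cv <- ctrl$value[ctrl$dof == d & ctrl$measure == m]
    av <- ex$value[ex$dof == d & ex$measure == m & ex$role == "affected"]
    uv <- ex$value[ex$dof == d & ex$measure == m & ex$role == "unaffected"]
    na_row <- tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    msd <- function(x) if (length(x)) c(mean(x), sd(x)) else c(NA_real_, NA_real_)
    wa <- if (length(av) >= 2 && length(cv) >= 2) welch_t(av, cv) else na_row
    wu <- if (length(uv) >= 2 && length(cv) >= 2) welch_t(uv, cv) else na_row
    d_or_na <- function(x, y) {
      if (length(x) >= 2 && length(y) >= 2) cohens_d(x, y) else NA_real_
    }
    tibble(
      joint = table2_rows$joint[i], measure = m, dof = d,
      control_mean = msd(cv)[1], control_sd = msd(cv)[2],
      affected_mean = msd(av)[1], affected_sd = msd(av)[2],
      unaffected_mean = msd(uv)[1], unaffected_sd = msd(uv)[2],
      p_affected = wa$p_value, p_unaffected = wu$p_value,
      d_affected = d_or_na(av, cv), d_unaffected = d_or_na(uv, cv)
    )
  })
}
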