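scale_to <- function(x, m, s) m + s * (x - mean(x)) / sd(x)

test_that("normality and variance-homogeneity screens behave", {
  expect_lt(normality_p(seq(0, 1, length.out = 80)), 0.05)
  set.seed(3)
  expect_gt(normality_p(rnorm(50)), 0.05)
  expect_error(normality_p(c(1, 2)), "at least 3")

  a <- c(1.2, 3.4, 2.2, 4.8, 0.7)
  expect_equal(variance_homogeneity_p(a, a), 1, tolerance = 1e-9)
  expect_error(variance_homogeneity_p(c(1, 2), a), "at least 3")
})

test_that("Welch t matches hand computation with Satterthwaite df", {
  a <- c(1.3, 2.4, 0.8, 1.9)
  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p_value, 1)

  set.seed(8)
  A <- scale_to(rnorm(16), 10, 2)
  B <- scale_to(rnorm(16), 12, 2)
  w <- welch_t(A, B)
  expect_equal(w$statistic, -2.828, tolerance = 1e-3)
  expect_equal(w$df, 30, tolerance = 1e-9)
  expect_equal(w$p_value, 2 * pt(-2.8284271, 30), tolerance = 1e-6)

  # scale invariance
  w10 <- welch_t(10 * A, 10 * B)
  expect_equal(w10$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(w10$df, w$df, tolerance = 1e-12)
  expect_equal(w10$p_value, w$p_value, tolerance = 1e-12)
})

test_that("chi-square uses margin-derived expected counts, no correction", {
  cs <- chi_square(matrix(c(30, 11, 48, 22), 2))
  # hand-computed: expected 28.81/49.19/12.19/20.81 -> 0.262
  expect_equal(cs$statistic, 0.262, tolerance = 1e-3)

  prop <- matrix(c(20, 10, 40, 20), 2)   # perfectly proportional
  cs <- chi_square(prop)
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p_value, 1, tolerance = 1e-12)

  expect_error(chi_square(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)),
               "empty row")
})

test_that("Cohen's d uses the pooled SD and keeps its sign", {
  a <- c(2, 4, 6)
  expect_equal(cohens_d(a, a), 0)

  set.seed(12)
  A <- scale_to(rnorm(78), 1.32, 0.55)
  B <- scale_to(rnorm(33), 0.97, 0.62)
  sp <- sqrt((77 * 0.55^2 + 32 * 0.62^2) / 109)
  expect_equal(cohens_d(A, B), (1.32 - 0.97) / sp, tolerance = 1e-9)
  expect_equal(cohens_d(A, B), 0.613, tolerance = 1e-3)
  expect_equal(cohens_d(A, B), -cohens_d(B, A))
})

test_that("wrapped tests agree with direct formula evaluation", {
  set.seed(19)
  for (i in 1:20) {
    A <- rnorm(sample(5:40, 1), sample(0:5, 1), runif(1, 0.5, 3))
    B <- rnorm(sample(5:40, 1), sample(0:5, 1), runif(1, 0.5, 3))
    na <- length(A); nb <- length(B)
    se <- sqrt(var(A) / na + var(B) / nb)
    tstat <- (mean(A) - mean(B)) / se
    df <- se^4 / ((var(A) / na)^2 / (na - 1) + (var(B) / nb)^2 / (nb - 1))
    w <- welch_t(A, B)
    expect_equal(w$statistic, tstat, tolerance = 1e-8)
    expect_equal(w$df, df, tolerance = 1e-8)
    expect_equal(w$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-8)

    tab <- matrix(sample(5:60, 4, replace = TRUE), 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square(tab)$statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-8)
  }
})

test_that("comparison tables keep the conventional row order and units", {
  set.seed(25)
  mk_sum <- function(n, speed) tibble::tibble(
    participant = paste0("p", 1:n), gait_speed = rnorm(n, speed, 0.1),
    stride_length = rnorm(n, 1.3, 0.1), step_width = rnorm(n, 0.09, 0.01),
    cadence = rnorm(n, 110, 5), double_support_pct = rnorm(n, 23, 2),
    n_cycles = 10, step_length_asymmetry_pct = abs(rnorm(n, 3, 1)))
  demo <- function(n) tibble::tibble(
    participant = paste0("p", 1:n), age = rnorm(n, 67, 5),
    sex = sample(c("M", "F"), n, replace = TRUE), bmi = rnorm(n, 24, 2))
  t1 <- build_table1(mk_sum(20, 1.24), mk_sum(15, 0.87), demo(20), demo(15))
  expect_equal(t1$parameter,
               c("Age (years)", "Sex (male/female)", "BMI (kg/m2)",
                 "Gait speed (m/s)", "Stride length (m)", "Step width (cm)",
                 "Cadence (steps/min)", "Double support (%cycle)",
                 "Step length asymmetry (%)"))
  # step width reported in cm
  expect_gt(t1$mean_a[t1$parameter == "Step width (cm)"], 5)
  expect_lt(t1$p_value[t1$parameter == "Gait speed (m/s)"], 0.05)

  # identical groups: all continuous rows p = 1
  s <- mk_sum(12, 1.0)
  t1 <- build_table1(s, s)
  expect_true(all(t1$p_value[t1$test == "welch_t"] == 1))
})

test_that("the peak table compares both experimental sides with controls", {
  set.seed(31)
  mk_peaks <- function(ids, shift = 0) {
    grid <- tidyr::expand_grid(
      participant = ids, side = c("L", "R"),
      tibble::tibble(dof = c("knee_angle", "knee_angle", "pelvis_tilt"),
                     measure = c("flexion", "extension", "peak")))
    dplyr::mutate(grid, value = dplyr::case_when(
      measure == "flexion" ~ rnorm(dplyr::n(), 50 + shift, 4),
      measure == "extension" ~ rnorm(dplyr::n(), 2, 2),
      TRUE ~ rnorm(dplyr::n(), -3, 2)), n_cycles = 10)
  }
  ctrl <- mk_peaks(paste0("c", 1:20))
  ex <- mk_peaks(paste0("e", 1:12), shift = -12)
  aff <- tibble::tibble(participant = paste0("e", 1:12),
                        affected_side = rep(c("L", "R"), 6))
  t2 <- build_table2(ctrl, ex, aff)
  expect_equal(nrow(t2), 15)
  expect_equal(t2$joint[1:3], rep("Pelvis", 3))
  knee <- t2[t2$dof == "knee_angle" & t2$measure == "flexion", ]
  expect_lt(knee$p_affected, 0.01)   # the injected 12 degree deficit
  expect_lt(knee$affected_mean, knee$control_mean)
})
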