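straight_walk <- function(speed = 1.2, dir = c(1, 0), n = 121) {
  time <- (seq_len(n) - 1) / 60
  fwd <- speed * time
  pel <- cbind(dir[1] * fwd, 0.95, dir[2] * fwd)
  mk_markers(time, list(pelvis = pel,
                        L_heel = cbind(dir[1] * fwd, 0.05, dir[2] * fwd + 0.05),
                        R_heel = cbind(dir[1] * fwd, 0.05, dir[2] * fwd - 0.05)))
}

test_that("walking direction follows the pelvis displacement", {
  expect_equal(as.numeric(walking_direction(straight_walk())), c(1, 0),
               tolerance = 1e-6)
  d <- walking_direction(straight_walk(dir = c(1, 1) / sqrt(2)))
  expect_equal(as.numeric(d), c(1, 1) / sqrt(2), tolerance = 1e-6)
  # lateral axis is the horizontal perpendicular
  expect_equal(sum(as.numeric(d) * attr(d, "lateral")), 0, tolerance = 1e-12)
  expect_error(walking_direction(straight_walk(speed = 0.1)), "too short")
})

test_that("gait speed is pelvis forward displacement over duration", {
  ms <- straight_walk(speed = 1.2)
  dir <- walking_direction(ms)
  expect_equal(gait_speed(ms, 0, 1, dir), 1.2, tolerance = 1e-9)

  still <- straight_walk(speed = 1.2)
  still$data$pelvis_X <- 0.6    # freeze the pelvis, keep heels moving
  expect_equal(gait_speed(still, 0, 1, dir), 0, tolerance = 1e-9)
})

test_that("stride, step and width follow heel positions at heel strikes", {
  time <- (0:120) / 60
  heel_x <- approx(c(0, 0.6, 1.4, 2), c(0, 0.66, 1.32, 1.8),
                   xout = time)$y
  ms <- mk_markers(time, list(
    pelvis = cbind(0.9 * time, 0.95, 0),
    L_heel = cbind(heel_x, 0.05, 0.05),
    R_heel = cbind(heel_x - 0.3, 0.05, -0.05)))
  dir <- walking_direction(ms)
  expect_equal(stride_length(ms, "L", 0, 1.4, dir), 1.32, tolerance = 1e-6)
  expect_equal(step_width(ms, 0.5, 0.5, dir), 0.10, tolerance = 1e-9)
  # both heels on the midline
  ms0 <- ms
  ms0$data$L_heel_Z <- 0; ms0$data$R_heel_Z <- 0
  expect_equal(step_width(ms0, 0.5, 0.5, dir), 0, tolerance = 1e-9)
})

test_that("cadence is 120 over cycle duration", {
  expect_equal(cadence(1.0), 120)
  expect_equal(cadence(2.0), 60)
  expect_equal(cadence(1.2207), 98.3, tolerance = 0.05)
  expect_error(cadence(0), "positive")
})

test_that("double support equals the interval-overlap oracle", {
  # stance 62% per foot, contralateral offset 50%: overlaps [50,62] and
  # [0,12] percent -> 24%
  ev <- dplyr::bind_rows(
    tibble::tibble(foot = "L", event = "heel_strike", time = c(0, 1, 2)),
    tibble::tibble(foot = "L", event = "toe_off", time = c(0.62, 1.62)),
    tibble::tibble(foot = "R", event = "heel_strike", time = c(-0.5, 0.5, 1.5)),
    tibble::tibble(foot = "R", event = "toe_off", time = c(0.12, 1.12, 2.12)))
  expect_equal(double_support_pct(ev, 0, 1, "L"), 24, tolerance = 1e-9)
  expect_equal(double_support_pct(ev, 0, 1, "L"),
               double_support_oracle(ev, 0, 1), tolerance = 0.05)

  # running pattern: stances never overlap
  run <- dplyr::bind_rows(
    tibble::tibble(foot = "L", event = "heel_strike", time = c(0, 1)),
    tibble::tibble(foot = "L", event = "toe_off", time = c(0.3, 1.3)),
    tibble::tibble(foot = "R", event = "heel_strike", time = c(-0.5, 0.5, 1.5)),
    tibble::tibble(foot = "R", event = "toe_off", time = c(-0.2, 0.8, 1.8)))
  expect_equal(double_support_pct(run, 0, 1, "L"), 0)

  # full-cycle bilateral stance
  full <- dplyr::bind_rows(
    tibble::tibble(foot = "L", event = "heel_strike", time = c(0, 1)),
    tibble::tibble(foot = "L", event = "toe_off", time = 1.01),
    tibble::tibble(foot = "R", event = "heel_strike", time = -0.01),
    tibble::tibble(foot = "R", event = "toe_off", time = 1.02))
  expect_equal(double_support_pct(full, 0, 1, "L"), 100, tolerance = 0.5)
})

test_that("step length asymmetry follows the percentage-difference formula", {
  expect_equal(step_length_asymmetry(0.5, 0.5), 0)
  expect_equal(step_length_asymmetry(0.55, 0.45), 20, tolerance = 1e-9)
  expect_equal(step_length_asymmetry(c(0.5, 0.6), c(0.45, 0.5)),
               step_length_asymmetry(c(0.45, 0.5), c(0.5, 0.6)))
  expect_error(step_length_asymmetry(0, 0), "undefined")
})

test_that("peak angles report signed extrema per measure", {
  curves <- cbind(knee_angle_l = c(seq(-3, 50.6, length.out = 51),
                                   seq(50.6, -3, length.out = 50)))
  pk <- peak_angles(curves)
  expect_equal(pk$value[pk$measure == "flexion"], 50.6)
  expect_equal(pk$value[pk$measure == "extension"], -3)
  expect_equal(unique(pk$side), "L")

  const <- cbind(ankle_angle_r = rep(5, 101))
  pk <- peak_angles(const)
  expect_equal(pk$value, c(5, 5))

  # flexion-type peak never below its antagonist
  co <- small_cohort(n = 1, cycles = 4, seed = 61)
  res <- run_trial(co$trials$markers[[1]], co$trials$angles[[1]])
  wide <- tidyr::pivot_wider(res$peaks, names_from = "measure",
                             values_from = "value",
                             id_cols = c("dof", "side", "foot", "cycle"))
  expect_true(all(wide$flexion >= wide$extension, na.rm = TRUE))
})

test_that("participant summary averages after the pooled 3 SD screen", {
  one <- tibble::tibble(participant = "p1", foot = "L", cycle = 1,
                        start = 0, end = 1, duration = 1,
                        gait_speed = 1.1, stride_length = 1.2,
                        step_width = 0.1, cadence = 110,
                        double_support_pct = 22, step_contra = 0.6,
                        step_ipsi = 0.6)
  s <- participant_summary(one)
  expect_equal(s$spatiotemporal$gait_speed, 1.1)
  expect_equal(s$spatiotemporal$stride_length, 1.2)
  expect_equal(s$spatiotemporal$step_length_asymmetry_pct, 0)

  # a 5 m stride artefact among ~N(1, 0.05) strides is screened out
  set.seed(9)
  n <- 21
  strides <- c(rnorm(20, 1, 0.05), 5)
  many <- tibble::tibble(
    participant = rep(c("p1", "p2"), c(11, 10)),
    foot = "L", cycle = seq_len(n), start = 0, end = 1, duration = 1,
    gait_speed = 1, stride_length = strides, step_width = 0.1,
    cadence = 110, double_support_pct = 22,
    step_contra = 0.5, step_ipsi = 0.5)
  s <- participant_summary(many)
  expect_true(all(s$spatiotemporal$stride_length < 1.2))
  # matches a direct pooled mean +/- 3 SD evaluation
  keep <- abs(strides - mean(strides)) <= 3 * sd(strides)
  expect_false(keep[n])
})

test_that("parameters are invariant to laboratory-frame rotation", {
  spec <- cohort_spec("control", n = 1, trials = 1, cycles_per_trial = 4,
                      marker_noise_sd = 0, angle_noise_sd = 0)
  set.seed(77)
  draws <- draw_participants(spec)
  d <- as.list(draws[1, ]); d$peaks <- draws$peaks[[1]]
  set.seed(123)
  t0 <- synth_trial(d, spec, heading = 0)
  set.seed(123)
  t1 <- synth_trial(d, spec, heading = 35 * pi / 180)
  r0 <- run_trial(t0$markers, t0$angles)
  r1 <- run_trial(t1$markers, t1$angles)
  for (col in c("gait_speed", "stride_length", "step_width",
                "double_support_pct")) {
    expect_equal(r0$params[[col]], r1$params[[col]], tolerance = 1e-6)
  }
})
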