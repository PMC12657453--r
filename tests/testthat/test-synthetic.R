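test_that("template calibration hits requested extrema exactly", {
  tpl <- gait_templates()$knee_angle
  ex <- template_extrema(tpl)
  same <- calibrate_template(tpl, ex["max"], ex["min"])
  expect_equal(same$a0, tpl$a0, tolerance = 1e-9)
  expect_equal(same$a, tpl$a, tolerance = 1e-9)

  cal <- calibrate_template(tpl, 50.60, 2.50)
  ex2 <- template_extrema(cal)
  expect_equal(unname(ex2["max"]), 50.60, tolerance = 1e-6)
  expect_equal(unname(ex2["min"]), 2.50, tolerance = 1e-6)

  # offset-only calibration for single-peak targets
  pel <- calibrate_template(gait_templates()$pelvis_tilt, -5.10)
  expect_equal(unname(template_extrema(pel)["max"]), -5.10,
               tolerance = 1e-6)

  expect_error(calibrate_template(tpl, 2, 10), "must exceed")
})

test_that("cohort specs validate internal consistency", {
  expect_s3_class(cohort_spec("koa", n = 5), "cohort_spec")
  bad <- tibble::tibble(
    parameter = c("gait_speed", "stride_length", "step_width_cm", "cadence",
                  "double_support_pct", "step_length_asymmetry_pct"),
    mean = c(1.2, 0.6, 9, 110, 23, 3),   # stride far from speed * 120/cadence
    sd = c(0.3, 0.3, 2, 10, 3, 1))
  expect_error(cohort_spec("control", n = 5, targets = bad), "inconsistent")
  bad2 <- bad
  bad2$mean <- c(1.2, 1.3, 9, 110, 55, 3)  # double support implies s > 0.75
  expect_error(cohort_spec("control", n = 5, targets = bad2),
               "stance fraction")
})

test_that("moment-matched draws reproduce the configured group structure", {
  spec <- cohort_spec("control", n = 30)
  set.seed(91)
  d <- draw_participants(spec)
  tg <- spec$targets
  for (p in c("gait_speed", "cadence", "step_width_cm",
              "double_support_pct")) {
    i <- which(tg$parameter == p)
    expect_equal(mean(d[[p]]), tg$mean[i], tolerance = 0.02 * tg$mean[i])
    expect_equal(sd(d[[p]]), tg$sd[i], tolerance = 0.15 * tg$sd[i])
  }
  # derived stance fractions stay inside the admissible band
  expect_true(all(d$stance_fraction > 0.5 & d$stance_fraction < 0.75))
  # speed = stride / cycle-duration by construction
  expect_equal(d$stride_length, d$gait_speed * 120 / d$cadence,
               tolerance = 1e-12)
})

test_that("two seeds give different draws with the same marginal structure", {
  spec <- cohort_spec("koa", n = 25)
  d1 <- draw_participants({set.seed(1); spec})
  set.seed(1); d1 <- draw_participants(spec)
  set.seed(2); d2 <- draw_participants(spec)
  expect_false(isTRUE(all.equal(d1$gait_speed, d2$gait_speed)))
  expect_equal(mean(d1$gait_speed), mean(d2$gait_speed), tolerance = 0.05)
})

test_that("generated trials are deterministic under a fixed seed", {
  spec <- cohort_spec("control", n = 2, trials = 1, cycles_per_trial = 2)
  c1 <- generate_cohort(spec, seed = 33)
  c2 <- generate_cohort(spec, seed = 33)
  expect_equal(c1$participants$gait_speed, c2$participants$gait_speed)
  expect_identical(c1$trials$markers[[1]]$data, c2$trials$markers[[1]]$data)
  expect_identical(c1$trials$angles[[1]]$data, c2$trials$angles[[1]]$data)

  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(spec, seed = 33, dir = d1)
  generate_cohort(spec, seed = 33, dir = d2)
  f <- list.files(d1)
  expect_true(length(f) >= 2 * 2 + 3)   # trc+mot per trial, 3 csvs
  for (fn in f) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
})

test_that("a written cohort directory reads back into the pipeline", {
  spec <- cohort_spec("koa", n = 2, trials = 1, cycles_per_trial = 3)
  dir <- withr::local_tempdir()
  co <- generate_cohort(spec, seed = 66, dir = dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$trials), 2)
  expect_equal(sort(back$participants$participant),
               sort(co$participants$participant))
  expect_true("affected_side" %in% names(back$participants))
  expect_equal(back$trials$markers[[1]]$data$L_heel_X,
               co$trials$markers[[1]]$data$L_heel_X, tolerance = 1e-6)
  res <- run_trial(back$trials$markers[[1]], back$trials$angles[[1]])
  expect_gt(nrow(res$params), 0)
})

test_that("cohort bookkeeping matches the spec", {
  co <- small_cohort(n = 2, trials = 1, cycles = 2, seed = 44)
  expect_equal(nrow(co$trials), 2)
  expect_equal(nrow(co$participants), 2)
  tr <- co$trials$events_truth[[1]]
  expect_true(all(c("heel_strike", "toe_off") %in% tr$event))
  # events strictly ordered per foot and type
  ord <- tr %>% dplyr::group_by(foot, event) %>%
    dplyr::summarise(ok = all(diff(time) > 0), .groups = "drop")
  expect_true(all(ord$ok))
})

test_that("calibrated waveforms reach their drawn peaks in the files", {
  spec <- cohort_spec("koa", n = 1, trials = 1, cycles_per_trial = 4,
                      marker_noise_sd = 0, angle_noise_sd = 0,
                      cycle_amp_jitter = 0)
  co <- generate_cohort(spec, seed = 55)
  p <- co$participants
  aff <- tolower(p$affected_side[1])
  target <- p$peaks[[1]][[paste0("knee_angle_", aff)]]
  knee <- co$trials$angles[[1]]$data[[paste0("knee_angle_", aff)]]
  # drop the trial's edge cycles where the waveform is truncated
  n <- length(knee)
  expect_equal(max(knee[round(n * 0.25):round(n * 0.75)]),
               unname(target["max"]), tolerance = 0.05)
})
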