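test_that("participant mean curve is the pointwise cycle mean", {
  m1 <- matrix(0, 101, 1, dimnames = list(NULL, "knee_angle_l"))
  m2 <- matrix(10, 101, 1, dimnames = list(NULL, "knee_angle_l"))
  cyc <- tibble::tibble(foot = "L", cycle = 1:2, start = 0:1, end = 1:2,
                        duration = 1, curves = list(m1, m2),
                        cycle_events = list(NULL, NULL))
  mc <- participant_mean_curve(cyc, "knee_angle_l")
  expect_equal(mc$value, rep(5, 101))
  expect_equal(participant_mean_curve(cyc[1, ], "knee_angle_l")$value,
               rep(0, 101))
})

test_that("the cycle mean converges to the waveform template", {
  # law of large numbers at 200 noisy cycles
  tpl <- gait_templates()$knee_angle
  set.seed(55)
  phase <- seq(0, 1, length.out = 101)
  base <- eval_template(tpl, phase)
  curves <- t(replicate(200, base + rnorm(101, 0, 2)))
  mc <- colMeans(curves)
  se <- 2 / sqrt(200)
  expect_lt(max(abs(mc - base)), 3 * se * 2.5)  # simultaneous margin
})

test_that("bootstrap bands are reproducible and degenerate correctly", {
  same <- matrix(rep(seq(0, 10, length.out = 101), each = 5), nrow = 5)
  b <- bootstrap_band(same, B = 200, seed = 1)
  expect_equal(b$lower, b$mean)
  expect_equal(b$upper, b$mean)

  set.seed(2)
  x <- matrix(rnorm(10 * 101), 10)
  b1 <- bootstrap_band(x, B = 300, seed = 42)
  b2 <- bootstrap_band(x, B = 300, seed = 42)
  expect_identical(b1, b2)

  expect_error(bootstrap_band(x[1, , drop = FALSE]), "at least 2")
  expect_warning(bootstrap_band(x, B = 50, seed = 1), "small")
})

test_that("band width matches the normal-approximation oracle", {
  set.seed(6)
  x <- matrix(rnorm(30 * 101), 30)
  b <- bootstrap_band(x, B = 2000, seed = 9)
  half <- mean((b$upper - b$lower) / 2)
  expect_equal(half, 1.96 / sqrt(30), tolerance = 0.15)
})

test_that("bands are equivariant under constant shifts", {
  set.seed(13)
  x <- matrix(rnorm(8 * 101), 8)
  b0 <- bootstrap_band(x, B = 400, seed = 3)
  b7 <- bootstrap_band(x + 7, B = 400, seed = 3)
  expect_equal(b7$mean, b0$mean + 7, tolerance = 1e-12)
  expect_equal(b7$lower, b0$lower + 7, tolerance = 1e-12)
  expect_equal(b7$upper, b0$upper + 7, tolerance = 1e-12)
})

test_that("a large constant offset flags the whole cycle", {
  set.seed(17)
  a <- matrix(rnorm(15 * 101, 10, 0.5), 15)
  b <- matrix(rnorm(15 * 101, 0, 0.5), 15)
  dr <- difference_regions(a, b, B = 500, seed = 5)
  expect_equal(nrow(dr$regions), 1)
  expect_equal(dr$regions$start, 0)
  expect_equal(dr$regions$end, 100)
  expect_true(all(dr$difference$flagged))
})

test_that("degenerate group sizes error and ordering does not matter", {
  x <- matrix(rnorm(6 * 101), 6)
  expect_error(difference_regions(x[1, , drop = FALSE], x), "at least 2")

  set.seed(23)
  a <- matrix(rnorm(10 * 101, 4), 10)   # clear separation
  b <- matrix(rnorm(12 * 101), 12)
  r1 <- difference_regions(a, b, B = 400, seed = 7)
  r2 <- difference_regions(a[sample(10), ], b[sample(12), ], B = 400,
                           seed = 7)
  expect_equal(r1$regions, r2$regions)
  expect_equal(r1$difference$diff, r2$difference$diff, tolerance = 1e-12)
})

test_that("short flagged runs are discarded by the run rule", {
  flags <- rep(FALSE, 101)
  flags[c(5, 20:24, 60:61)] <- TRUE
  regions <- kneegait:::merge_regions(flags, 0:100, min_run = 3)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, 19)
  expect_equal(regions$end, 23)
})

test_that("null flag rate is near the nominal level (scaled check)", {
  set.seed(29)
  rate <- mean(replicate(40, {
    a <- matrix(rnorm(15 * 101), 15)
    b <- matrix(rnorm(15 * 101), 15)
    mean(difference_regions(a, b, B = 300)$difference$flagged)
  }))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("tidiers expose per-point and summary views", {
  set.seed(31)
  a <- matrix(rnorm(8 * 101, 2), 8)
  b <- matrix(rnorm(8 * 101), 8)
  dr <- difference_regions(a, b, B = 300, seed = 11)
  td <- tidy(dr)
  expect_equal(nrow(td), 101)
  expect_named(td, c("percent", "diff", "lower", "upper", "flagged"))
  gl <- glance(dr)
  expect_equal(gl$n_a, 8)
  expect_equal(gl$n_regions, nrow(dr$regions))
  p <- ggplot2::autoplot(dr)
  expect_s3_class(p, "ggplot")
})
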