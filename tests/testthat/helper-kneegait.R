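# shared fixtures and independent oracles, built in code

# write a small hand-typed TRC fixture and return its path
tiny_trc_path <- function() {
  path <- withr::local_tempfile(fileext = ".trc",
                                .local_envir = parent.frame())
  lines <- c(
    "PathFileType\t4\t(X/Y/Z)\ttiny.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "60\t60\t3\t2\tmm\t60\t1\t3",
    "Frame#\tTime\tL_heel\t\t\tR_heel\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2",
    "1\t0.000000\t1.5\t2.5\t3.5\t10\t20\t30",
    "2\t0.016667\t4.5\t5.5\t6.5\t40\t50\t60",
    "3\t0.033333\t7.5\t8.5\t9.5\t70\t80\t90"
  )
  writeLines(lines, path)
  path
}

tiny_mot_path <- function() {
  path <- withr::local_tempfile(fileext = ".mot",
                                .local_envir = parent.frame())
  writeLines(c(
    "tiny.mot", "version=1", "nRows=4", "nColumns=2", "inDegrees=yes",
    "endheader",
    "time\tknee_angle_r",
    "0.000000\t0.000000",
    "0.016667\t10.000000",
    "0.033333\t20.000000",
    "0.050000\t10.000000"
  ), path)
  path
}

# independent Savitzky-Golay oracle: per-point least-squares polynomial fit
# on the window truncated at the series bounds, via lm
savgol_oracle <- function(x, window, order) {
  n <- length(x)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    ord <- min(order, length(idx) - 1)
    fit <- stats::lm(y ~ stats::poly(t, ord, raw = TRUE),
                     data = data.frame(t = idx - i, y = x[idx]))
    unname(stats::predict(fit, newdata = data.frame(t = 0)))
  }, numeric(1))
}

# brute-force double-support oracle: sample stance occupancy on a fine grid
double_support_oracle <- function(events, start, end, n_grid = 20000L) {
  tg <- seq(start, end, length.out = n_grid)
  tg <- tg[-n_grid]
  in_stance <- function(foot) {
    si <- kneegait::stance_intervals(events, foot)
    occ <- rep(FALSE, length(tg))
    for (i in seq_len(nrow(si))) {
      occ <- occ | (tg >= si$start[i] & tg < si$end[i])
    }
    occ
  }
  100 * mean(in_stance("L") & in_stance("R"))
}

# small synthetic cohort for module tests
small_cohort <- function(group = "control", n = 2, trials = 1, cycles = 4,
                         seed = 11, ...) {
  spec <- cohort_spec(group, n = n, trials = trials,
                      cycles_per_trial = cycles, ...)
  generate_cohort(spec, seed = seed)
}

# match each truth event to its nearest detection; errors in frames
event_errors_frames <- function(detected, truth, frame_rate = 60) {
  purrr::map_dfr(c("L", "R"), function(f) {
    purrr::map_dfr(c("heel_strike", "toe_off"), function(e) {
      tt <- truth$time[truth$foot == f & truth$event == e]
      dd <- detected$time[detected$foot == f & detected$event == e]
      if (length(tt) == 0) return(tibble::tibble())
      tibble::tibble(
        foot = f, event = e,
        err = vapply(tt, function(t) {
          if (length(dd) == 0) Inf else min(abs(dd - t)) * frame_rate
        }, numeric(1)))
    })
  })
}

# build a marker_set (metres, vertical Y) from named x/y/z coordinate lists
mk_markers <- function(time, pos, frame_rate = 60) {
  d <- tibble::tibble(frame = seq_along(time), time = time)
  for (nm in names(pos)) {
    d[[paste0(nm, "_X")]] <- pos[[nm]][, 1]
    d[[paste0(nm, "_Y")]] <- pos[[nm]][, 2]
    d[[paste0(nm, "_Z")]] <- pos[[nm]][, 3]
  }
  kneegait::marker_set(d, frame_rate = frame_rate, units = "m")
}

# pipeline run over a generated cohort, pooled per-cycle tables
pool_cohort <- function(cohort, config = gait_config()) {
  params <- list(); peaks <- list()
  for (i in seq_len(nrow(cohort$trials))) {
    res <- run_trial(cohort$trials$markers[[i]], cohort$trials$angles[[i]],
                     config)
    if (nrow(res$params)) {
      params[[i]] <- dplyr::mutate(res$params,
                                   participant = cohort$trials$participant[i])
    }
    if (nrow(res$peaks)) {
      pk <- dplyr::mutate(res$peaks,
                          participant = cohort$trials$participant[i],
                          side = dplyr::coalesce(side, foot))
      peaks[[i]] <- dplyr::filter(pk, side == foot)
    }
  }
  list(params = dplyr::bind_rows(params), peaks = dplyr::bind_rows(peaks))
}
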