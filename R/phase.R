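# Phase-wise analysis of time-normalized kinematic curves: participant mean
# curves, bootstrap confidence bands, and significant-region detection.

# coerce participant curves to a participants x grid matrix
curves_to_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  if (is.data.frame(curves)) {
    # long tibble: participant, percent, value
    assert_that(all(c("participant", "percent", "value") %in% names(curves)),
                "curve tibble needs participant/percent/value columns")
    w <- tidyr::pivot_wider(curves, names_from = "percent",
                            values_from = "value")
    return(as.matrix(w[, -1, drop = FALSE]))
  }
  if (is.list(curves)) return(do.call(rbind, curves))
  abort("cannot interpret 'curves'", class = "kneegait_error")
}

#' Participant mean curve
#'
#' Pointwise mean of one degree of freedom's normalized curves over a
#' participant's accepted cycles.
#'
#' @param cycles Cycle tibble from [segment_cycles()] (QC-accepted rows).
#' @param dof Degree-of-freedom column name within the cycle curves.
#' @return Tibble with `percent` and `value`.
#' @export
participant_mean_curve <- function(cycles, dof) {
  assert_that(nrow(cycles) >= 1, "no cycles to average")
  mats <- purrr::map(cycles$curves, ~ .x[, dof])
  m <- do.call(rbind, mats)
  tibble(percent = seq(0, 100, length.out = ncol(m)),
         value = colMeans(m, na.rm = TRUE))
}

# finite-sample widening of the percentile interval (expanded percentile):
# the bootstrap distribution of a mean is narrower than the sampling
# distribution by sqrt((n-1)/n) and uses z rather than t quantiles; the
# adjusted level alpha' restores nominal coverage.
expanded_alpha <- function(alpha, n) {
  2 * pnorm(-sqrt(n / (n - 1)) * qt(1 - alpha / 2, df = n - 1))
}

boot_group_means <- function(mat, B) {
  n <- nrow(mat)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  W <- matrix(0, nrow = B, ncol = n)
  for (b in seq_len(B)) {
    tb <- tabulate(idx[b, ], nbins = n)
    W[b, ] <- tb / n
  }
  W %*% mat
}

#' Bootstrap confidence band for a group mean curve
#'
#' Resamples participants with replacement `B` times and takes pointwise
#' quantile intervals of the resampled group means. The default interval is
#' the expanded percentile interval (percentile quantiles at a slightly
#' widened level that restores nominal small-sample coverage for a mean);
#' `ci_type = "percentile"` gives the plain percentile interval.
#'
#' @param curves Participant curves: a participants x grid matrix, a list
#'   of equal-length vectors, or a long tibble with `participant`,
#'   `percent`, `value`.
#' @param B Bootstrap replicates (default 1000; below 100 a warning).
#' @param alpha Pointwise level (default 0.05 for 95% bands).
#' @param seed Optional RNG seed making the band reproducible.
#' @param ci_type `"expanded"` (default) or `"percentile"`.
#' @return A `curve_band` tibble: `percent`, `mean`, `lower`, `upper`.
#' @export
bootstrap_band <- function(curves, B = 1000L, alpha = 0.05, seed = NULL,
                           ci_type = c("expanded", "percentile")) {
  ci_type <- match.arg(ci_type)
  mat <- curves_to_matrix(curves)
  n <- nrow(mat)
  assert_that(n >= 2, "bootstrap band needs at least 2 participants")
  if (B < 100) warn(sprintf("B = %d bootstrap replicates is very small", B))
  if (!is.null(seed)) set.seed(seed)
  bm <- boot_group_means(mat, B)
  a <- if (ci_type == "expanded") expanded_alpha(alpha, n) else alpha
  qs <- apply(bm, 2, quantile, probs = c(a / 2, 1 - a / 2), names = FALSE)
  out <- tibble(
    percent = seq(0, 100, length.out = ncol(mat)),
    mean = colMeans(mat),
    lower = pmin(qs[1, ], colMeans(mat)),
    upper = pmax(qs[2, ], colMeans(mat))
  )
  class(out) <- c("curve_band", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "B") <- B
  attr(out, "n") <- n
  out
}

merge_regions <- function(flagged, percent, min_run) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tibble(start = percent[starts[keep]], end = percent[ends[keep]])
}

#' Significant-difference regions between two groups of curves
#'
#' Bootstraps the pointwise difference of group mean curves by resampling
#' participants with replacement within each group. A grid point is flagged
#' when the quantile interval of the difference excludes zero; flagged
#' points are merged into contiguous runs, and runs shorter than `min_run`
#' grid points are discarded, yielding the conventional "X%-Y%" region
#' notation. Resampling participants (not cycles) avoids pseudo-replication
#' from the many cycles each participant contributes.
#'
#' @param curves_a,curves_b Participant curves per group (see
#'   [bootstrap_band()] for accepted forms).
#' @param B Bootstrap replicates (default 1000).
#' @param alpha Pointwise level (default 0.05).
#' @param min_run Minimum run length in grid points (default 3).
#' @param seed Optional RNG seed.
#' @param ci_type `"expanded"` (default) or `"percentile"`.
#' @return A `phase_comparison` object: `$difference` (tibble with
#'   `percent`, `diff`, `lower`, `upper`, `flagged`), `$regions` (tibble of
#'   `start`/`end` percents), `$band_a`/`$band_b` (group bands from the same
#'   resamples), and the settings.
#' @export
difference_regions <- function(curves_a, curves_b, B = 1000L, alpha = 0.05,
                               min_run = 3L, seed = NULL,
                               ci_type = c("expanded", "percentile")) {
  ci_type <- match.arg(ci_type)
  ma <- curves_to_matrix(curves_a)
  mb <- curves_to_matrix(curves_b)
  na <- nrow(ma); nb <- nrow(mb)
  assert_that(na >= 2 && nb >= 2,
              "difference regions need at least 2 participants per group")
  assert_that(ncol(ma) == ncol(mb), "groups must share the percentage grid")
  if (!is.null(seed)) set.seed(seed)
  bma <- boot_group_means(ma, B)
  bmb <- boot_group_means(mb, B)
  bdiff <- bma - bmb
  grid <- seq(0, 100, length.out = ncol(ma))

  if (ci_type == "expanded") {
    # pointwise Satterthwaite df and bootstrap-narrowness correction
    va <- apply(ma, 2, var) / na
    vb <- apply(mb, 2, var) / nb
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
    shrink <- sqrt((va * (na - 1) / na + vb * (nb - 1) / nb) / (va + vb))
    shrink[!is.finite(shrink) | shrink == 0] <- 1
    # bootstrap sd of the mean difference underestimates the sampling sd
    # by 'shrink'; widen the percentile level so the effective threshold
    # equals the t-based one on the plug-in scale
    a_pt <- 2 * pnorm(-qt(1 - alpha / 2, df) / shrink)
  } else {
    a_pt <- rep(alpha, ncol(ma))
  }
  lo <- vapply(seq_len(ncol(ma)), function(j)
    quantile(bdiff[, j], a_pt[j] / 2, names = FALSE), numeric(1))
  hi <- vapply(seq_len(ncol(ma)), function(j)
    quantile(bdiff[, j], 1 - a_pt[j] / 2, names = FALSE), numeric(1))
  flagged <- lo > 0 | hi < 0

  band_from <- function(bm, mat, n) {
    a <- if (ci_type == "expanded") expanded_alpha(alpha, n) else alpha
    qs <- apply(bm, 2, quantile, probs = c(a / 2, 1 - a / 2), names = FALSE)
    out <- tibble(percent = grid, mean = colMeans(mat),
                  lower = pmin(qs[1, ], colMeans(mat)),
                  upper = pmax(qs[2, ], colMeans(mat)))
    class(out) <- c("curve_band", class(out))
    out
  }

  structure(
    list(
      difference = tibble(percent = grid, diff = colMeans(ma) - colMeans(mb),
                          lower = lo, upper = hi, flagged = flagged),
      regions = merge_regions(flagged, grid, min_run),
      band_a = band_from(bma, ma, na),
      band_b = band_from(bmb, mb, nb),
      alpha = alpha, B = B, min_run = min_run, ci_type = ci_type,
      n_a = na, n_b = nb
    ),
    class = "phase_comparison"
  )
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf(
    "<phase_comparison> n = %d vs %d, B = %d, alpha = %g, min_run = %d\n",
    x$n_a, x$n_b, x$B, x$alpha, x$min_run))
  if (nrow(x$regions) == 0) {
    cat("no significant regions\n")
  } else {
    cat("significant regions:",
        paste(sprintf("%g%%-%g%%", x$regions$start, x$regions$end),
              collapse = ", "), "\n")
  }
  invisible(x)
}
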