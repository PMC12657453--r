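# broom-style tidiers for the package's result objects.

#' Tidy a phase comparison
#'
#' One row per gait-cycle percentage with the mean difference, its
#' bootstrap interval and the significance flag.
#'
#' @param x A `phase_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phase_comparison <- function(x, ...) {
  x$difference
}

#' Glance at a phase comparison
#'
#' @param x A `phase_comparison`.
#' @param ... Unused.
#' @return One-row tibble with group sizes, settings, number of
#'   significant regions and total flagged cycle percentage.
#' @export
glance.phase_comparison <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, B = x$B, alpha = x$alpha,
         min_run = x$min_run, ci_type = x$ci_type,
         n_regions = nrow(x$regions),
         flagged_pct = 100 * mean(x$difference$flagged))
}

#' Tidy a cohort comparison
#'
#' The spatiotemporal/demographics comparison table (one row per
#' parameter).
#'
#' @param x A `cohort_comparison` (see [run_cohort()]).
#' @param table Which table: `"table1"` (default) or `"table2"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cohort_comparison <- function(x, table = c("table1", "table2"), ...) {
  x[[match.arg(table)]]
}

#' Glance at a cohort comparison
#'
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @return One-row tibble with participant and retained-cycle counts.
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(n_a = x$cycle_counts$n_participants[1],
         n_b = x$cycle_counts$n_participants[2],
         cycles_a = x$cycle_counts$cycles_retained[1],
         cycles_b = x$cycle_counts$cycles_retained[2],
         n_significant_table1 = sum(x$table1$p_value < 0.05, na.rm = TRUE),
         n_significant_table2 = sum(x$table2$p_affected < 0.05,
                                    na.rm = TRUE))
}
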