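# ggplot2 visualisations for bands and phase comparisons.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_rect
#'   labs theme_minimal annotate
NULL

#' @export
ggplot2::autoplot

#' Plot a bootstrap confidence band
#'
#' Mean curve with its pointwise bootstrap confidence ribbon over the gait
#' cycle.
#'
#' @param object A `curve_band` (see [bootstrap_band()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curve_band <- function(object, ...) {
  ggplot(object, aes(x = .data$percent)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "steelblue", alpha = 0.3) +
    geom_line(aes(y = .data$mean), colour = "steelblue") +
    labs(x = "Gait cycle (%)", y = "Angle (deg)") +
    theme_minimal()
}

#' Plot a phase-wise group comparison
#'
#' Both group mean curves with their bootstrap confidence ribbons, with
#' the statistically significant regions shaded, in the conventional
#' curve-comparison layout.
#'
#' @param object A `phase_comparison` (see [difference_regions()]).
#' @param labels Length-2 group labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_comparison <- function(object, labels = c("Group A", "Group B"),
                                      ...) {
  ba <- mutate(object$band_a, group = labels[1])
  bb <- mutate(object$band_b, group = labels[2])
  d <- bind_rows(ba, bb)
  p <- ggplot(d, aes(x = .data$percent, colour = .data$group,
                     fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                alpha = 0.25, colour = NA) +
    geom_line(aes(y = .data$mean)) +
    labs(x = "Gait cycle (%)", y = "Angle (deg)", colour = NULL,
         fill = NULL) +
    theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + geom_rect(
      data = object$regions,
      aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey40", alpha = 0.15)
  }
  p
}

#' Plot normalized cycle curves of one degree of freedom
#'
#' Spaghetti plot of all accepted cycles for one dof family, one line per
#' cycle, coloured by foot.
#'
#' @param cycles Cycle tibble from [segment_cycles()] / [run_trial()].
#' @param dof Dof family name (side suffix added per cycle foot when
#'   needed).
#' @return A ggplot object.
#' @export
plot_cycle_curves <- function(cycles, dof) {
  d <- purrr::map_dfr(seq_len(nrow(cycles)), function(i) {
    col <- if (dof %in% colnames(cycles$curves[[i]])) dof else
      paste0(dof, "_", tolower(cycles$foot[i]))
    if (!col %in% colnames(cycles$curves[[i]])) return(tibble())
    tibble(cycle = paste(cycles$foot[i], cycles$cycle[i]),
           foot = cycles$foot[i],
           percent = seq(0, 100, length.out = nrow(cycles$curves[[i]])),
           value = cycles$curves[[i]][, col])
  })
  ggplot(d, aes(.data$percent, .data$value, group = .data$cycle,
                colour = .data$foot)) +
    geom_line(alpha = 0.6) +
    labs(x = "Gait cycle (%)", y = "Angle (deg)", colour = "Foot",
         title = dof) +
    theme_minimal()
}
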