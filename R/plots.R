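# ggplot2 helpers for the main result types.

#' Plot ancestry painting along the chromosome
#'
#' One horizontal bar per haplotype, coloured by assigned ancestry;
#' `UNDEFINED` tracts are grey. Module boundaries can be overlaid.
#'
#' @param p a `painted_set` or tract tibble.
#' @param modules optional module map to draw as background shading.
#' @return a ggplot object.
#' @export
plot_painting <- function(p, modules = NULL) {
  tracts <- if (inherits(p, "painted_set")) p$tracts else p
  tracts <- tracts %>%
    mutate(haplotype_id = factor(.data$haplotype_id,
                                 levels = rev(sort(unique(.data$haplotype_id)))))
  g <- ggplot2::ggplot(tracts)
  if (!is.null(modules)) {
    g <- g + ggplot2::geom_rect(
      data = modules,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf,
      fill = ifelse(modules$masked, "grey85", "grey95"), colour = NA)
  }
  g +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$haplotype_id, yend = .data$haplotype_id,
                   colour = .data$label),
      linewidth = 3) +
    ggplot2::scale_colour_manual(
      values = painting_palette(setdiff(unique(tracts$label), UNDEFINED_LABEL)),
      na.value = "grey70") +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "ancestry") +
    ggplot2::theme_minimal()
}

painting_palette <- function(groups) {
  base <- c("#E69F00", "#56B4E9", "#009E73", "#CC79A7", "#0072B2", "#D55E00")
  pal <- setNames(rep(base, length.out = length(groups)), groups)
  c(pal, setNames("grey75", UNDEFINED_LABEL))
}

#' @export
autoplot.painted_set <- function(object, ...) plot_painting(object, ...)

#' Plot windowed statistics along the chromosome
#'
#' Line plots of one or more window statistics, faceted by statistic, with
#' one colour per population pair.
#'
#' @param ws a tibble from [windowed_stats()].
#' @param stats which statistic columns to show.
#' @return a ggplot object.
#' @export
plot_window_stats <- function(ws, stats = c("pi1", "dxy", "da", "fst")) {
  long <- ws %>%
    mutate(pair = ifelse(is.na(.data$pop2), .data$pop1,
                         paste(.data$pop1, .data$pop2, sep = "-")),
           mid = (.data$start + .data$end) / 2) %>%
    tidyr::pivot_longer(dplyr::all_of(stats),
                        names_to = "stat", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value,
                                     colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window midpoint (bp)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
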