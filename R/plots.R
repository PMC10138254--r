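# ggplot2 displays for the main result types.

#' Plot a wavelet-variance profile
#'
#' Estimates with confidence intervals per level, annotated with the
#' frequency band of each level.
#'
#' @param object A `wvar_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wvar_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$level),
                                       y = .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_discrete(labels = paste0(object$level, "\n",
                                              object$band)) +
    ggplot2::labs(x = "decomposition level (frequency band)",
                  y = "wavelet variance",
                  title = sprintf("Wavelet-variance profile (N = %s, %s)",
                                  attr(object, "N"), attr(object, "filter"))) +
    ggplot2::theme_minimal()
}

#' Plot a multiresolution analysis
#'
#' Stacked per-level detail series and the smooth, on a common time
#' axis.
#'
#' @param object A `modwt_mra` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modwt_mra <- function(object, ...) {
  d <- tidy.modwt_mra(object)
  d$component <- factor(d$component, levels = unique(d$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Multiresolution analysis") +
    ggplot2::theme_minimal()
}

#' Cell-mean interaction plot for a wavelet-variance table
#'
#' Group-by-condition mean wavelet variance (with standard-error bars)
#' for one region and level — the display conventionally used for a
#' 2x2 interaction.
#'
#' @param table A [cohort_wvar()] table.
#' @param roi Region to display.
#' @param level Decomposition level to display.
#' @return A ggplot object.
#' @export
plot_cell_means <- function(table, roi, level) {
  d <- table[table$roi == roi & table$level == level, ]
  if (nrow(d) == 0) stop("no rows for the requested roi/level", call. = FALSE)
  s <- d |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(mean = mean(.data$wvar),
                     se = stats::sd(.data$wvar) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean,
                                  group = .data$group,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = NULL, y = "wavelet variance",
                  title = sprintf("%s, level %d", roi, level)) +
    ggplot2::theme_minimal()
}
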