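#' Plot the RD distribution of a classified catalog
#'
#' Histogram plus density of element RD values with the class thresholds as
#' vertical dashed lines; when the input-track RD is available its density is
#' overlaid as a dashed curve (the processing-bias control).
#'
#' @param object A `pre_classification`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pre_classification <- function(object, bins = 30, ...) {
  thr <- attr(object, "thresholds")
  df <- tibble::as_tibble(unclass(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rd)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_density(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = unname(thr), linetype = "dashed") +
    ggplot2::labs(x = "relative difference (mutant vs control)",
                  y = "density") +
    ggplot2::theme_classic()
  if (!all(is.na(df$rd_input))) {
    p <- p + ggplot2::geom_density(ggplot2::aes(x = .data$rd_input),
                                   linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a cumulative occupancy profile
#'
#' @param object A `profile_matrix` from [build_profile()].
#' @param ... Unused.
#' @return A ggplot of the mean profile across peaks.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  mp <- mean_profile(object)
  ggplot2::ggplot(mp, ggplot2::aes(x = .data$offset, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from summit (bp)", y = "mean density") +
    ggplot2::theme_classic()
}

#' @export
autoplot.fitted_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "offset from summit (bp)", y = "fitted value") +
    ggplot2::theme_classic()
}

#' Plot the genotype profile comparison
#'
#' Fitted genotype curves with their flat background reference lines, plus
#' the smoothed mutant-minus-control difference curve underneath.
#'
#' @param comparison A [compare_profiles()] result.
#' @return A ggplot (two panels via facetting).
#' @export
plot_profile_comparison <- function(comparison) {
  curves <- dplyr::bind_rows(
    mutant = tibble::as_tibble(unclass(comparison$curves$mutant)),
    control = tibble::as_tibble(unclass(comparison$curves$control)),
    .id = "genotype"
  )
  diff <- tibble::as_tibble(unclass(comparison$difference))
  curves$panel <- "occupancy"
  diff$panel <- "difference"
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = comparison$background,
                        ggplot2::aes(yintercept = .data$level,
                                     colour = .data$genotype),
                        linetype = "dashed") +
    ggplot2::geom_line(data = diff,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "offset from summit (bp)", y = NULL) +
    ggplot2::theme_classic()
}
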