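# ggplot2 figures for the main result types

#' Diel anthrophony profile by urban category
#'
#' Line plot of mean 1-2 kHz power per hour for each urban category, with
#' an optional horizontal threshold reference (e.g. the 55 dB
#' outdoor-disturbance level when the data are calibrated).
#'
#' @param profile Tibble from [hourly_category_profile()].
#' @param threshold_db Optional reference level drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_diel_profile <- function(profile, threshold_db = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$hour, y = .data$mean_db,
                                    colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 4)) +
    ggplot2::labs(x = "Hour of day", y = "Average power 1-2 kHz (dB)",
                  colour = "Urban") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_db)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_db,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Ordination plot of a soundscape PCA
#'
#' Scores on the first two components, optionally colored by a grouping
#' vector, with loading segments overlaid (scaled to the score cloud).
#'
#' @param object A [soundscape_pca()] result.
#' @param groups Optional grouping vector (one value per row).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.soundscape_pca <- function(object, groups = NULL, ...) {
  sc <- tibble::tibble(PC1 = object$scores[, 1], PC2 = object$scores[, 2])
  if (!is.null(groups)) sc$group <- groups
  lab <- sprintf("PC%d (%.0f%%)", 1:2, 100 * object$prop_var[1:2])
  scale <- 0.8 * max(abs(sc$PC1), abs(sc$PC2)) /
    max(abs(object$loadings[, 1:2]))
  ld <- tibble::tibble(
    variable = rownames(object$loadings) %||%
      paste0("V", seq_len(nrow(object$loadings))),
    x = object$loadings[, 1] * scale,
    y = object$loadings[, 2] * scale
  )
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
  p +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          inherit.aes = FALSE, colour = "grey40",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$variable),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Cross-medium band correlation plot
#'
#' Bar chart of per-band R-squared between above- and below-water average
#' power, highlighting bands significant at the chosen level.
#'
#' @param cross Tibble from [cross_medium_regression()].
#' @return A ggplot object.
#' @export
plot_cross_medium <- function(cross) {
  dat <- dplyr::filter(cross, .data$band != "full")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$band, y = .data$r.squared,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Frequency band (kHz)", y = expression(R^2),
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
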