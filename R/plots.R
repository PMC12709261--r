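# ggplot2 front-ends for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.fe_surface <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$free_energy), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mid, .data$y_mid,
                                   fill = .data$free_energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "F (kT)", direction = -1) +
    ggplot2::labs(x = "Eccentricity", y = "β-strand proportion") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.interaction_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$res_i, .data$res_j,
                                   fill = .data$frequency_score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "score (nm⁻¹)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Residue", y = "Residue",
                  title = paste0(object$mode, " interaction map")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ss_pca <- function(object, ...) {
  ggplot2::ggplot(object$projections,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$frame)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "frame") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-frame shape descriptors
#'
#' Eccentricity and total radius of gyration over time.
#'
#' @param series Output of [shape_series()].
#' @return A ggplot object.
#' @export
plot_shape_series <- function(series) {
  df <- tidyr::pivot_longer(
    series[, c("frame", "rg_total", "eccentricity")],
    -"frame", names_to = "descriptor", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~descriptor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Frame", y = NULL) +
    ggplot2::theme_minimal()
}
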