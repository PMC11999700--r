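#' Plot a cell table as a point map
#'
#' @param table Cell table.
#' @param colour_by Column mapped to colour (default `cell_type`).
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_tissue <- function(table, colour_by = "cell_type", size = 0.3) {
  ggplot2::ggplot(table, ggplot2::aes(.data$x_um, .data$y_um,
                                      colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = size) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~donor_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Plot islet features along pseudotime
#'
#' @param pseudotime Tibble from [compute_pseudotime()] (optionally with
#'   `stage`).
#' @param features Islet feature tibble.
#' @param feature Feature column to display (e.g. `"feat_CD8T"`).
#' @return A ggplot object.
#' @export
plot_pseudotime <- function(pseudotime, features, feature = "feat_CD8T") {
  df <- dplyr::left_join(pseudotime, features, by = "islet_id")
  colour <- if ("stage" %in% names(df)) "stage" else "cluster"
  ggplot2::ggplot(df, ggplot2::aes(.data$pseudotime, .data[[feature]])) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour]]))) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "pseudotime", y = feature, colour = colour) +
    ggplot2::theme_minimal()
}

#' Heatmap of CN adjacency frequencies
#'
#' @param adjacency Tibble from [adjacency_matrix()].
#' @return A ggplot object.
#' @export
plot_adjacency <- function(adjacency) {
  ggplot2::ggplot(adjacency,
                  ggplot2::aes(.data$dest, .data$source,
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "destination CN", y = "source CN",
                  fill = "adjacency\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of per-donor two-level slopes
#'
#' @param slopes Tibble from [fit_two_level_hlm()] with `donor = NULL`.
#' @return A ggplot object.
#' @export
plot_lobular_slopes <- function(slopes) {
  df <- slopes[slopes$term == "x", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$donor_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "slope (z pseudotime per z abundance)", y = "donor") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hlm_fit <- function(object, ...) {
  df <- object$fixed
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::theme_minimal()
}
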