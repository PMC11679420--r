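# ggplot2 methods for the result types.

#' Plot a point cloud
#'
#' Side view (z along the row, y height) of a labeled point cloud, colored
#' by label; thin the cloud with `sample_n` for quick looks.
#'
#' @param cloud Point cloud tibble.
#' @param sample_n Maximum number of points drawn (sampled deterministically).
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, sample_n = 20000L) {
  assert_cloud(cloud)
  if (nrow(cloud) > sample_n) {
    cloud <- cloud[round(seq(1, nrow(cloud), length.out = sample_n)), ]
  }
  if (!"label" %in% names(cloud)) cloud$label <- "unknown"
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$z, y = .data$y,
                                      colour = .data$label)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z along row (m)", y = "height (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname height_density_profile
#' @param object A `height_density_profile`.
#' @param ... Unused.
#' @export
autoplot.height_density_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$y_mid <- (df$y_lo + df$y_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_density, y = .data$y_mid)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("point density (points" ~ m^-3 * ")"),
                  y = "canopy height (m)") +
    ggplot2::theme_minimal()
}

#' @rdname thickness_density_profile
#' @param object A `thickness_density_profile`.
#' @param ... Unused.
#' @export
autoplot.thickness_density_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$section, y = .data$percentage,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "canopy thickness section",
                  y = "share of total density (%)") +
    ggplot2::theme_minimal()
}

#' @rdname run_experiment
#' @param object A `report_bundle`.
#' @export
autoplot.report_bundle <- function(object, ...) {
  b <- object$biometrics %>%
    tidyr::pivot_longer(dplyr::all_of(c("VCH", "VV", "VCY", "VSP")),
                        names_to = "estimator", values_to = "volume")
  ggplot2::ggplot(b, ggplot2::aes(x = .data$estimator, y = .data$volume,
                                  fill = .data$state)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = expression("apparent canopy volume" ~ (m^3)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
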