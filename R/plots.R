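# ggplot2 visualisations for the main result types.

#' Plot a ROM hull
#'
#' @param object a [rom_hull()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rom_hull <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elbow, y = .data$wrist)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3, colour = "steelblue") +
    ggplot2::labs(x = "elbow angle (deg)", y = "wrist angle (deg)",
                  title = "Elbow-wrist range of motion") +
    ggplot2::theme_minimal()
}

#' Plot a ROM sweep surface
#'
#' Tile map of a swept quantity over the (elbow, wrist) grid.
#'
#' @param object an `avi_sweep` from [sweep_rom()].
#' @param metric column to map (default `"static_margin"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.avi_sweep <- function(object, metric = "static_margin", ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elbow, y = .data$wrist,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "elbow angle (deg)", y = "wrist angle (deg)",
                  fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot the normalized CG range of a sweep
#'
#' The region traced by the body-length-normalized CG across the ROM
#' (convex hull of the swept CG positions).
#'
#' @param sweep an `avi_sweep`.
#' @return a ggplot object.
#' @export
plot_cg_range <- function(sweep) {
  df <- tibble::as_tibble(sweep)
  idx <- grDevices::chull(df$x_cg_norm, df$z_cg_norm)
  hull <- df[idx, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_cg_norm, y = .data$z_cg_norm)) +
    ggplot2::geom_polygon(data = hull, fill = "darkorange", alpha = 0.3) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "normalized CG x (fraction of body length)",
                  y = "normalized CG z") +
    ggplot2::theme_minimal()
}

#' Plot Monte-Carlo likelihood-ratio distributions
#'
#' Histograms of the likelihood ratio simulated under the fitted BM and OU
#' models with the observed ratio as a dashed line.
#'
#' @param object a `pmc_result` from [pmc_bootstrap()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pmc_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(model = "BM", lr = object$lr_bm),
    tibble::tibble(model = "OU", lr = object$lr_ou)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lr, fill = .data$model)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 50) +
    ggplot2::geom_vline(xintercept = object$lr_obs, linetype = "dashed") +
    ggplot2::labs(x = "likelihood ratio 2(logL_OU - logL_BM)", y = "count") +
    ggplot2::theme_minimal()
}
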