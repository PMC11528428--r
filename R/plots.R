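#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recovered pattern mask
#'
#' Renders the occupied raster, optionally overlaying molecular positions
#' and the ground-truth outline.
#'
#' @param object A `pattern_mask`.
#' @param points Optional coordinates to overlay (nm).
#' @param truth Optional ground-truth polygon to outline (nm).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_mask <- function(object, points = NULL, truth = NULL, ...) {
  occ <- object$occupancy
  df <- tidyr::expand_grid(
    ix = seq_len(nrow(occ)),
    iy = seq_len(ncol(occ)))
  df$x <- (object$origin[1L] + (df$ix - 0.5) * object$pixel_nm) / 1000
  df$y <- (object$origin[2L] + (df$iy - 0.5) * object$pixel_nm) / 1000
  df$occupied <- as.vector(occ[cbind(df$ix, df$iy)])
  p <- ggplot2::ggplot(df[df$occupied, ], ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = "#2a9d8f") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s pattern: %.1f µm² (μ_NND %.1f nm)",
                                  object$method, object$area_um2, object$mu_nnd_nm)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    xy <- as_xy(points)
    p <- p + ggplot2::geom_point(
      data = data.frame(x = xy[, 1L] / 1000, y = xy[, 2L] / 1000),
      size = 0.1, alpha = 0.4, colour = "#264653")
  }
  if (!is.null(truth)) {
    t_xy <- as_xy(truth, "truth")
    p <- p + ggplot2::geom_path(
      data = data.frame(x = c(t_xy[, 1L], t_xy[1L, 1L]) / 1000,
                        y = c(t_xy[, 2L], t_xy[1L, 2L]) / 1000),
      colour = "black", linewidth = 0.3)
  }
  p
}

#' Plot a proximity-threshold scan
#'
#' Difference between the experimental log K and the CSR reference as a
#' function of the proximity threshold; the maximum marks the data-driven
#' pairing criterion.
#'
#' @param object An `smlmeq_scan` from [threshold_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smlmeq_scan <- function(object, ...) {
  best <- attr(object, "best_threshold_nm")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold_nm, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "proximity threshold (nm)",
                  y = expression(log ~ K - log ~ K[CSR]),
                  title = sprintf("Threshold scan (max at %g nm)", best)) +
    ggplot2::theme_minimal()
}

#' Plot a QPI histogram with its mixture fit
#'
#' @param object A `qpi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qpi_fit <- function(object, ...) {
  h <- object$histogram
  xs <- seq(0, max(h$mid), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble(x = xs, k = factor(k),
           y = object$peak_weights[k] *
             dnorm(xs, object$peak_means[k], object$peak_sigmas[k]))
  })
  # rescale mixture to the histogram's density scale
  comp$y <- comp$y / max(1e-12, sum(object$peak_weights))
  bar_w <- if (nrow(h) > 1L) h$mid[2L] - h$mid[1L] else 1
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = bar_w, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$y, colour = .data$k)) +
    ggplot2::labs(x = expression(QPI ~ (s^-1)), y = "density",
                  colour = "component",
                  title = sprintf("Unit QPI = %.4g 1/s", object$unit_qpi_s_inv)) +
    ggplot2::theme_minimal()
}

#' Heatmap of validation-grid deviations
#'
#' @param object An `smlmeq_grid` from [run_validation_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smlmeq_grid <- function(object, ...) {
  summ <- summarize_validation_grid(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$density),
                                     y = factor(.data$log_ka),
                                     fill = .data$mean_deviation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_deviation)),
                       size = 3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", limits = c(-0.5, 0.5),
                                  oob = scales_squish) +
    ggplot2::labs(x = expression(density ~ (mu * m^-2)),
                  y = expression(log ~ K[a]),
                  fill = "recovered - input") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1L]), range[2L])
}
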