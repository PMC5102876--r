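#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$fraction,
                                       color = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "threshold", y = "fraction of frames",
                  title = "Threshold accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.track_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(object, frame_id = .data$frame_id,
                     roi_side = .data$roi_side,
                     confident = as.numeric(.data$confident)),
    -"frame_id", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_id, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL, title = "Tracking trace") +
    ggplot2::theme_minimal()
}

#' Overlay a pose (or annotation row) on a frame
#'
#' @param image image matrix.
#' @param pose a `pose_estimate`, a one-row annotation tibble, or `NULL`.
#' @return a ggplot object.
#' @export
plot_pose <- function(image, pose = NULL) {
  h <- nrow(image); w <- ncol(image)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(image), xmin = -0.5,
                               xmax = w - 0.5, ymin = -(h - 0.5), ymax = 0.5) +
    ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5), ylim = c(-(h - 0.5), 0.5)) +
    ggplot2::theme_void()
  if (!is.null(pose)) {
    pts <- if (inherits(pose, "pose_estimate")) {
      pose$configuration
    } else {
      tibble::tibble(part = c("left", "center", "right", "shaft"),
                     x = c(pose$left_x, pose$center_x, pose$right_x, pose$shaft_x),
                     y = c(pose$left_y, pose$center_y, pose$right_y, pose$shaft_y))
    }
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = -.data$y,
                                              color = .data$part), size = 3) +
      ggplot2::scale_color_brewer(palette = "Set1")
  }
  p
}
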