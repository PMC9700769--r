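# ggplot2 views of images, skeletons and metric series.

img_to_df <- function(img) {
  tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img)
  )
}

#' Plot a grayscale frame with an optional skeleton overlay
#'
#' @param img Numeric matrix, intensities in `[0, 255]`.
#' @param skel Optional logical skeleton to overlay.
#' @return A ggplot.
#' @export
plot_frame <- function(img, skel = NULL) {
  assert_image(img)
  p <- ggplot2::ggplot(img_to_df(img), ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(skel)) {
    px <- which(skel, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(row = px[, 1], col = px[, 2]),
      colour = "red", size = 0.1
    )
  }
  p
}

#' Plot per-frame metric series
#'
#' @param metrics Frame-record tibble from [analyze_frames()] or
#'   [run_pipeline()].
#' @param metric Column to plot (default `"total_area"`, the headline
#'   contour-area series).
#' @return A ggplot of metric versus frame.
#' @export
plot_metric_series <- function(metrics, metric = "total_area") {
  x <- if ("time" %in% names(metrics)) "time" else "frame_id"
  ggplot2::ggplot(metrics, ggplot2::aes(.data[[x]], .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = x, y = paste(metric, "(arbitrary units)"))
}

#' @describeIn compare_series Plot the two mean +/- SEM curves and the
#'   difference ribbon of a comparison.
#' @param object A `cord_comparison`.
#' @param ... Unused.
#' @export
autoplot.cord_comparison <- function(object, ...) {
  d <- object$by_time
  long <- dplyr::bind_rows(
    tibble::tibble(time = d$time, series = "a", mean = d$mean_a, sem = d$sem_a),
    tibble::tibble(time = d$time, series = "b", mean = d$mean_b, sem = d$sem_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$mean,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time point",
                  y = paste(object$metric, "(arbitrary units)"))
}
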