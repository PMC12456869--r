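## broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a match evaluation into per-match rows
#'
#' @param x A [evaluate_matches()] result.
#' @param ... Unused.
#' @return Tibble with one row per evaluated match: `distance_px`, `band`,
#'   `true_positive`.
#' @export
tidy.match_evaluation <- function(x, ...) {
  b <- x$bands
  tibble::tibble(
    distance_px = x$distances,
    band = cut(x$distances, c(-Inf, b[1], b[2], Inf),
               labels = c("good", "moderate", "outlier"), right = FALSE),
    true_positive = x$distances < x$threshold_px)
}

#' @rdname tidy.match_evaluation
#' @export
glance.match_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, dropped = x$dropped, rmse_px = x$rmse_px,
                 rmse_mm = x$rmse_mm, precision_pct = x$precision_pct,
                 threshold_px = x$threshold_px,
                 good = unname(x$band_counts["good"]),
                 moderate = unname(x$band_counts["moderate"]),
                 outlier = unname(x$band_counts["outlier"]))
}

#' @rdname tidy.match_evaluation
#' @export
glance.dice_result <- function(x, ...) {
  tibble::tibble(dice = x$dice, size_x = x$size_x, size_y = x$size_y,
                 intersection = x$intersection)
}

#' @rdname tidy.match_evaluation
#' @export
glance.landmark_report <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, rmse_px = x$rmse_px,
                 rmse_mm = x$rmse_mm)
}

#' @rdname tidy.match_evaluation
#' @export
tidy.landmark_report <- function(x, ...) {
  tibble::tibble(distance_px = x$distances)
}

#' Tidy a quiver grid into one row per unmasked block
#'
#' @param x A [quiver_downsample()] result.
#' @param ... Unused.
#' @return Tibble with block centers (`x`, `y`), `orientation` (degrees)
#'   and `depol_mean`.
#' @export
tidy.quiver_grid <- function(x, ...) {
  keep <- !x$masked
  cx <- x$cx[keep]; cy <- x$cy[keep]
  ori <- x$orientation[keep]; dp <- x$depol_mean[keep]
  tibble::tibble(x = cx, y = cy, orientation = ori, depol_mean = dp)
}

#' Plot a quiver grid
#'
#' Renders each unmasked block as a line segment along its mean azimuth,
#' mirroring the standard masked quiver display of fiber orientation.
#'
#' @param object A `quiver_grid`.
#' @param length Segment length in pixels (default 80% of the block size).
#' @param ... Unused.
#' @return A ggplot object (y axis reversed to match image coordinates).
#' @export
autoplot.quiver_grid <- function(object, length = 0.8 * object$block, ...) {
  df <- tidy.quiver_grid(object)
  th <- df$orientation * pi / 180
  df$xend <- df$x + length / 2 * cos(th); df$x0 <- df$x - length / 2 * cos(th)
  df$yend <- df$y - length / 2 * sin(th); df$y0 <- df$y + length / 2 * sin(th)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$orientation)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_gradientn(
      colours = c("#d7191c", "#fdae61", "#abd9e9", "#2c7bb6", "#d7191c"),
      limits = c(0, 180), name = "azimuth (deg)") +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a match evaluation
#'
#' Histogram of match distances colored by quality band, with the
#' true-positive threshold marked.
#'
#' @param object A `match_evaluation`.
#' @param binwidth Histogram bin width in pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.match_evaluation <- function(object, binwidth = NULL, ...) {
  df <- tidy.match_evaluation(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_px,
                                   fill = .data$band)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold_px,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(good = "#1a9641",
                                          moderate = "#fdae61",
                                          outlier = "#d7191c"),
                               drop = FALSE) +
    ggplot2::labs(x = "match distance (px)", y = "count",
                  title = sprintf("RMSE %.2f px, precision %.1f%%",
                                  object$rmse_px, object$precision_pct))
}

#' @importFrom ggplot2 .data
NULL
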