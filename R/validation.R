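## Alignment validation: dice overlap of dilated border masks and RMSE over
## corresponding reference landmarks, with pixel-to-mm conversion.

#' Dice overlap of two masks
#'
#' `Dice(X, Y) = 2 |X intersect Y| / (|X| + |Y|)`.  Both masks empty is a
#' 0/0 case: the result is `NaN` with a warning rather than a silently
#' plausible number.
#'
#' @param x,y `border_mask` objects or logical matrices of the same shape.
#' @return Object of class `dice_result`: `dice`, `size_x`, `size_y`,
#'   `intersection`.
#' @export
dice <- function(x, y) {
  mx <- if (inherits(x, "border_mask")) x$mask else x
  my <- if (inherits(y, "border_mask")) y$mask else y
  stopifnot(is.logical(mx) || all(mx %in% c(0, 1)),
            all(dim(mx) == dim(my)))
  nx <- sum(mx); ny <- sum(my); ni <- sum(mx & my)
  if (nx + ny == 0) {
    warning("both masks empty; dice undefined")
    d <- NaN
  } else d <- 2 * ni / (nx + ny)
  structure(list(dice = d, size_x = nx, size_y = ny, intersection = ni),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> dice = %.4f (|X| = %d, |Y| = %d, |X n Y| = %d)\n",
              x$dice, x$size_x, x$size_y, x$intersection))
  invisible(x)
}

#' RMSE between corresponding landmark sets
#'
#' Root mean square of the per-point Euclidean distances between
#' `points_a[i]` and `points_b[i]`, reported in pixels and (when a pixel
#' pitch is given) in mm.
#'
#' @param points_a,points_b Data frames with columns `x`, `y`; equal length
#'   `>= 1`.
#' @param pixel_pitch mm per pixel (optional).
#' @return Object of class `landmark_report`: `n_points`, `rmse_px`,
#'   `rmse_mm`, `distances`.
#' @export
landmark_rmse <- function(points_a, points_b, pixel_pitch = NULL) {
  if (nrow(points_a) != nrow(points_b))
    stop("point sets differ in length: ", nrow(points_a), " vs ",
         nrow(points_b))
  if (nrow(points_a) < 1) stop("need at least one point pair")
  d <- sqrt((points_a$x - points_b$x)^2 + (points_a$y - points_b$y)^2)
  rmse <- sqrt(mean(d^2))
  structure(list(n_points = length(d), rmse_px = rmse,
                 rmse_mm = if (is.null(pixel_pitch)) NA_real_
                           else rmse * pixel_pitch,
                 distances = d),
            class = "landmark_report")
}

#' @export
print.landmark_report <- function(x, ...) {
  cat(sprintf("<landmark_report> n = %d, RMSE = %.3f px%s\n", x$n_points,
              x$rmse_px,
              if (is.na(x$rmse_mm)) "" else sprintf(" (%.3f mm)", x$rmse_mm)))
  invisible(x)
}

#' Border overlay report
#'
#' Computes the dice overlap of a reference and a test border mask and
#' writes a color overlay PNG (reference in red, test in green, their
#' intersection in yellow, background dark).
#'
#' @param reference_border,test_border `border_mask` objects in the same
#'   frame.
#' @param output Path of the PNG to write (`NULL` to skip writing).
#' @return The [dice()] result, invisibly carrying the output path as
#'   attribute `overlay`.
#' @export
border_overlay_report <- function(reference_border, test_border,
                                  output = NULL) {
  mr <- reference_border$mask; mt <- test_border$mask
  stopifnot(all(dim(mr) == dim(mt)))
  d <- dice(reference_border, test_border)
  if (!is.null(output)) {
    h <- nrow(mr); w <- ncol(mr)
    img <- array(0.12, dim = c(h, w, 3))
    img[, , 1][mr] <- 1; img[, , 2][mr] <- 0.1; img[, , 3][mr] <- 0.1
    img[, , 1][mt] <- 0.1; img[, , 2][mt] <- 1; img[, , 3][mt] <- 0.1
    both <- mr & mt
    img[, , 1][both] <- 1; img[, , 2][both] <- 1; img[, , 3][both] <- 0.1
    png::writePNG(img, output)
    attr(d, "overlay") <- output
  }
  invisible(d)
}

#' Field-of-view coverage arithmetic
#'
#' Areas of the imager's field of view and of a section, both given as
#' `c(width, height)` in cm, and the minimum number of fields needed by
#' area ratio.
#'
#' @param fov_cm Field of view `c(w, h)` in cm (imager default 2.5 x 2.1).
#' @param section_cm Section `c(w, h)` in cm (whole-brain-section default
#'   10 x 7).
#' @return List: `fov_area_cm2`, `section_area_cm2`, `area_ratio`,
#'   `n_fields_min` (ratio rounded to nearest integer).
#' @export
fov_coverage <- function(fov_cm = c(2.5, 2.1), section_cm = c(10, 7)) {
  fa <- prod(fov_cm); sa <- prod(section_cm)
  list(fov_area_cm2 = fa, section_area_cm2 = sa, area_ratio = sa / fa,
       n_fields_min = round(sa / fa))
}
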