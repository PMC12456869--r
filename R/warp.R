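#' Deformation fields
#'
#' A `deformation_field` is the pipeline's alignment currency: a dense
#' backward mapping from reference (fixed) pixel coordinates to moving-frame
#' coordinates.  `x_map[y + 1, x + 1]` and `y_map[y + 1, x + 1]` give the
#' moving-frame position of fixed pixel `(x, y)` (0-based, pixel centers at
#' integers).  `mask` marks the domain on which the field is defined.
#'
#' @param x_map,y_map Numeric matrices of equal dimension.
#' @param mask Logical matrix (default: all finite entries).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(x_map, y_map, mask = NULL) {
  stopifnot(is.matrix(x_map), is.matrix(y_map),
            all(dim(x_map) == dim(y_map)))
  if (is.null(mask)) mask <- is.finite(x_map) & is.finite(y_map)
  stopifnot(all(dim(mask) == dim(x_map)))
  structure(list(x_map = x_map, y_map = y_map, mask = mask),
            class = "deformation_field")
}

#' @rdname deformation_field
#' @param h,w Frame height and width in pixels.
#' @export
identity_field <- function(h, w) {
  deformation_field(grid_x(h, w), grid_y(h, w))
}

#' @rdname deformation_field
#' @param dx,dy Translation in pixels (moving = fixed + (dx, dy)).
#' @export
translation_field <- function(h, w, dx, dy) {
  deformation_field(grid_x(h, w) + dx, grid_y(h, w) + dy)
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$x_map)
  disp <- sqrt((x$x_map - grid_x(d[1], d[2]))^2 +
               (x$y_map - grid_y(d[1], d[2]))^2)
  cat(sprintf("<deformation_field> %d x %d, domain %.1f%%, mean |u| = %.2f px\n",
              d[1], d[2], 100 * mean(x$mask),
              mean(disp[x$mask])))
  invisible(x)
}

## ---- thin-plate spline ----------------------------------------------------

tps_kernel <- function(r2) {
  u <- numeric(length(r2))
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos]) / 2   # r^2 log r = r^2 log(r^2)/2
  u
}

## Fit a 2-D TPS mapping (x_f, y_f) -> (x_m, y_m).  lambda >= 0 is the
## bending-energy weight; lambda = 0 interpolates the landmarks exactly.
tps_solve <- function(xf, yf, xm, ym, lambda = 0) {
  n <- length(xf)
  if (anyDuplicated(cbind(xf, yf)))
    stop("duplicate fixed landmarks at rows: ",
         paste(which(duplicated(cbind(xf, yf))), collapse = ", "))
  K <- tps_kernel(outer(xf, xf, "-")^2 + outer(yf, yf, "-")^2)
  dim(K) <- c(n, n)
  P <- cbind(1, xf, yf)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(cbind(xm, ym), matrix(0, 3, 2))
  coef <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular thin-plate-spline system (collinear or duplicate ",
         "landmarks); fixed points:\n",
         paste(sprintf("  (%g, %g)", xf, yf), collapse = "\n"))
  })
  list(w = coef[seq_len(n), , drop = FALSE],
       a = coef[n + 1:3, , drop = FALSE], xf = xf, yf = yf)
}

tps_eval <- function(fit, x, y) {
  n <- length(fit$xf)
  ## evaluate in blocks to bound memory on large frames
  out_x <- numeric(length(x)); out_y <- numeric(length(x))
  block <- max(1L, floor(4e6 / n))
  for (s in seq(1, length(x), by = block)) {
    idx <- s:min(s + block - 1, length(x))
    U <- tps_kernel(outer(x[idx], fit$xf, "-")^2 + outer(y[idx], fit$yf, "-")^2)
    dim(U) <- c(length(idx), n)
    out_x[idx] <- fit$a[1, 1] + fit$a[2, 1] * x[idx] + fit$a[3, 1] * y[idx] +
      U %*% fit$w[, 1]
    out_y[idx] <- fit$a[1, 2] + fit$a[2, 2] * x[idx] + fit$a[3, 2] * y[idx] +
      U %*% fit$w[, 2]
  }
  list(x = out_x, y = out_y)
}

#' Fit a landmark-constrained elastic deformation
#'
#' Fits a thin-plate spline mapping fixed-frame landmark positions onto their
#' moving-frame counterparts, minimising landmark error plus
#' `lambda` times the bending energy, and rasterizes it over the reference
#' frame as a dense [deformation_field()].  With `lambda = 0` the spline
#' interpolates every landmark exactly and reproduces affine relationships to
#' machine precision.
#'
#' @param pairs Data frame with columns `x_fixed`, `y_fixed`, `x_moving`,
#'   `y_moving` (0-based pixels); at least 3 non-collinear fixed points.
#' @param frame `c(h, w)` of the reference frame to rasterize over.
#' @param lambda Bending-energy weight, `>= 0`.
#' @param grid_spacing Rasterization grid step in pixels.  The spline is
#'   evaluated exactly at grid nodes and interpolated bilinearly between
#'   them; `1` (default) evaluates every pixel exactly.
#' @return A [deformation_field()] covering the full frame.
#' @export
fit_landmark_warp <- function(pairs, frame, lambda = 0, grid_spacing = 1) {
  stopifnot(all(c("x_fixed", "y_fixed", "x_moving", "y_moving") %in%
                names(pairs)),
            length(frame) == 2, grid_spacing >= 1)
  if (nrow(pairs) < 3)
    stop("need at least 3 landmark pairs for a 2-D fit, got ", nrow(pairs))
  fit <- tps_solve(pairs$x_fixed, pairs$y_fixed,
                   pairs$x_moving, pairs$y_moving, lambda = lambda)
  h <- frame[1]; w <- frame[2]
  if (grid_spacing == 1) {
    gx <- grid_x(h, w); gy <- grid_y(h, w)
    ev <- tps_eval(fit, as.vector(gx), as.vector(gy))
    fld <- deformation_field(matrix(ev$x, h, w), matrix(ev$y, h, w))
    attr(fld, "tps") <- fit
    return(fld)
  }
  ## coarse exact evaluation, bilinear upsampling (affine parts stay exact)
  xs <- unique(c(seq(0, w - 1, by = grid_spacing), w - 1))
  ys <- unique(c(seq(0, h - 1, by = grid_spacing), h - 1))
  cg <- expand.grid(y = ys, x = xs)
  ev <- tps_eval(fit, cg$x, cg$y)
  cx <- matrix(ev$x, length(ys), length(xs))
  cy <- matrix(ev$y, length(ys), length(xs))
  ## map full-frame coords into the coarse grid's index space
  ix <- stats::approx(xs, seq_along(xs) - 1, xout = 0:(w - 1))$y
  iy <- stats::approx(ys, seq_along(ys) - 1, xout = 0:(h - 1))$y
  IX <- matrix(rep(ix, each = h), h, w)
  IY <- matrix(rep(iy, times = w), h, w)
  fld <- deformation_field(
    matrix(sample_image(cx, as.vector(IX), as.vector(IY)), h, w),
    matrix(sample_image(cy, as.vector(IX), as.vector(IY)), h, w))
  attr(fld, "tps") <- fit
  fld
}

#' Warp an image through a deformation field
#'
#' Backward resampling: `out(x, y) = image(x_map(x, y), y_map(x, y))`.
#' Samples falling outside the image (or outside the field's domain) are set
#' to `fill` and marked invalid in the returned mask.
#'
#' @param image Numeric matrix in the moving frame.
#' @param field A [deformation_field()] over the output (reference) frame.
#' @param interpolation `"bilinear"` or `"nearest"` (use nearest for
#'   categorical label tiles).
#' @param fill Fill value for invalid output pixels.
#' @return List with `image` (warped matrix) and `mask` (logical validity).
#' @export
apply_warp <- function(image, field, interpolation = c("bilinear", "nearest"),
                       fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  d <- dim(field$x_map)
  v <- sample_image(image, as.vector(field$x_map), as.vector(field$y_map),
                    fill = NA_real_, method = interpolation)
  out <- matrix(v, d[1], d[2])
  mask <- !is.na(out) & field$mask
  out[!mask] <- fill
  list(image = out, mask = mask)
}

#' Map points through a deformation field
#'
#' Bilinear interpolation of the field's coordinate maps at each query point.
#' Points outside the field's domain are flagged, not dropped.
#'
#' @param field A [deformation_field()].
#' @param points Data frame with columns `x`, `y` (0-based pixels).
#' @return A tibble with columns `x`, `y` (mapped coordinates) and
#'   `in_domain` (logical).
#' @export
map_points <- function(field, points) {
  stopifnot(all(c("x", "y") %in% names(points)))
  fit <- attr(field, "tps")
  if (!is.null(fit)) {
    ## fitted fields carry their spline model: evaluate it analytically so
    ## landmarks are honoured exactly, not through grid interpolation
    ev <- tps_eval(fit, points$x, points$y)
    mx <- ev$x; my <- ev$y
  } else {
    mx <- sample_image(field$x_map, points$x, points$y)
    my <- sample_image(field$y_map, points$x, points$y)
  }
  dom <- sample_image(field$mask * 1, points$x, points$y, method = "nearest")
  tibble::tibble(x = mx, y = my,
                 in_domain = !is.na(mx) & !is.na(my) &
                   !is.na(dom) & dom > 0)
}

#' Compose two deformation fields
#'
#' `compose_fields(f, g)` maps reference coordinates through `f` then `g`:
#' the stain-to-stain transfer operation (reference -> first stain composed
#' with first stain -> second stain).  Points whose image under `f` falls
#' outside `g`'s domain are masked out.
#'
#' @param first,second [deformation_field()] objects; `first`'s range should
#'   lie (mostly) within `second`'s domain.
#' @return A [deformation_field()] over `first`'s frame.
#' @export
compose_fields <- function(first, second) {
  d <- dim(first$x_map)
  fx <- as.vector(first$x_map); fy <- as.vector(first$y_map)
  gx <- sample_image(second$x_map, fx, fy)
  gy <- sample_image(second$y_map, fx, fy)
  dom <- sample_image(second$mask * 1, fx, fy, method = "nearest")
  mask <- matrix(!is.na(gx) & !is.na(gy) & !is.na(dom) & dom > 0, d[1], d[2]) &
    first$mask
  if (!any(mask)) stop("composed deformation field has an empty domain")
  deformation_field(matrix(gx, d[1], d[2]), matrix(gy, d[1], d[2]), mask)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration: for each target pixel `u` in the moving frame, find
#' `X` with `field(X) = u`.  Used to turn forward ground-truth constructions
#' into the canonical backward representation.
#'
#' @param field A [deformation_field()] (assumed smooth and fold-free).
#' @param h,w Dimensions of the output (moving) frame; default the field's.
#' @param tol Convergence tolerance in pixels.
#' @param max_iter Iteration cap.
#' @return A [deformation_field()] mapping moving coordinates back to fixed.
#' @export
invert_field <- function(field, h = nrow(field$x_map), w = ncol(field$x_map),
                         tol = 0.01, max_iter = 50) {
  ux <- as.vector(grid_x(h, w)); uy <- as.vector(grid_y(h, w))
  ## displacement of the forward field, interpolable at fractional positions
  d <- dim(field$x_map)
  dxf <- field$x_map - grid_x(d[1], d[2])
  dyf <- field$y_map - grid_y(d[1], d[2])
  x <- ux; y <- uy
  for (i in seq_len(max_iter)) {
    ddx <- sample_image(dxf, x, y, fill = 0)
    ddy <- sample_image(dyf, x, y, fill = 0)
    nx <- ux - ddx; ny <- uy - ddy
    step <- max(abs(nx - x), abs(ny - y))
    x <- nx; y <- ny
    if (step < tol) break
  }
  ## valid where the forward field maps the recovered point near the target
  ex <- sample_image(field$x_map, x, y)
  ey <- sample_image(field$y_map, x, y)
  mask <- matrix(!is.na(ex) & !is.na(ey) &
                 sqrt((ex - ux)^2 + (ey - uy)^2) < 10 * tol + 0.5, h, w)
  xm <- matrix(x, h, w); ym <- matrix(y, h, w)
  xm[!mask] <- NA_real_; ym[!mask] <- NA_real_   # keep diverged iterates out
  deformation_field(xm, ym, mask)
}

## Jacobian-determinant check (no folding) on a field's domain interior.
field_jacobian_ok <- function(field) {
  xm <- field$x_map; ym <- field$y_map
  h <- nrow(xm); w <- ncol(xm)
  dxx <- (xm[, 3:w] - xm[, 1:(w - 2)]) / 2
  dyx <- (ym[, 3:w] - ym[, 1:(w - 2)]) / 2
  dxy <- (xm[3:h, ] - xm[1:(h - 2), ]) / 2
  dyy <- (ym[3:h, ] - ym[1:(h - 2), ]) / 2
  J <- dxx[2:(h - 1), ] * dyy[, 2:(w - 1)] - dxy[, 2:(w - 1)] * dyx[2:(h - 1), ]
  m <- field$mask[2:(h - 1), 2:(w - 1)]
  all(J[m] > 0, na.rm = TRUE)
}
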