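#' @keywords internal
"_PACKAGE"

## Coordinate convention, fixed project-wide: 0-based, x = column, y = row,
## pixel centers at integer coordinates.  A value at (x, y) lives at
## img[y + 1, x + 1] in the underlying R matrix.

#' Sample an image at fractional coordinates
#'
#' Bilinear (or nearest-neighbour) backward sampling of a 2-D scalar field at
#' arbitrary fractional positions, using the package-wide 0-based,
#' pixel-centers-at-integers convention.
#'
#' @param img Numeric matrix (rows = y, columns = x).
#' @param x,y Numeric vectors of equal length, 0-based coordinates.
#' @param fill Value returned for out-of-bounds samples (default `NA`).
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric vector of sampled values, `fill` where out of bounds.
#' @export
sample_image <- function(img, x, y, fill = NA_real_,
                         method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  stopifnot(length(x) == length(y))
  out <- rep(as.numeric(fill), length(x))
  if (method == "nearest") {
    xi <- round(x); yi <- round(y)
    ok <- !is.na(xi) & !is.na(yi) & xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    return(out)
  }
  ok <- !is.na(x) & !is.na(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
  out
}

## Full-frame coordinate grids (0-based), as h x w matrices.
grid_x <- function(h, w) matrix(rep(0:(w - 1), each = h), h, w)
grid_y <- function(h, w) matrix(rep(0:(h - 1), times = w), h, w)

## Forward rigid map about a pivot: X' = R(theta) (X - pivot) + pivot + t.
## Returns a function taking (x, y) vectors and giving list(x, y).
rigid_map <- function(dx, dy, theta_deg, pivot = c(0, 0)) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  function(x, y) {
    xr <- x - pivot[1]; yr <- y - pivot[2]
    list(x = ct * xr - st * yr + pivot[1] + dx,
         y = st * xr + ct * yr + pivot[2] + dy)
  }
}

rigid_inverse <- function(dx, dy, theta_deg, pivot = c(0, 0)) {
  th <- -theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  function(x, y) {
    xr <- x - pivot[1] - dx; yr <- y - pivot[2] - dy
    list(x = ct * xr - st * yr + pivot[1],
         y = st * xr + ct * yr + pivot[2])
  }
}

## Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Band-limited scalar noise field in [0, 1]: white noise smoothed with a
## Gaussian of the given sigma, then min-max rescaled.  Uses the caller's RNG.
smooth_noise <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- as_mat(EBImage::gblur(z, sigma = sigma,
                             radius = 2 * ceiling(3 * sigma) + 1))
  rng <- range(z)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, h, w))
  (z - rng[1]) / diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## strip EBImage's Image class down to a plain base matrix
as_mat <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))
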