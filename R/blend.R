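## Sigmoid distance-weighted blending of aligned tiles into a mosaic.
## Each tile's per-pixel weight rises from 0 at its footprint border to 1 at
## distance d_max inside it, so seams fade over a gradient of length d_max.

#' Tile record
#'
#' One tile channel already warped into the reference frame, together with
#' its validity footprint.
#'
#' @param image Numeric matrix in the reference frame.
#' @param mask Logical footprint; `image` must be finite wherever `mask`.
#' @param tile_id Integer identifier.
#' @return Object of class `tile_record`.
#' @export
tile_record <- function(image, mask, tile_id = 1L) {
  stopifnot(is.matrix(image), all(dim(mask) == dim(image)))
  mask <- mask & is.finite(image)
  structure(list(image = image, mask = mask, tile_id = as.integer(tile_id)),
            class = "tile_record")
}

#' Distance to the tile border
#'
#' Euclidean distance from each valid pixel to the nearest invalid
#' (no-signal) pixel of the footprint.  A footprint with no invalid pixel at
#' all has `d_border = Inf` everywhere (its blend weight is then 1).
#'
#' @param mask Logical validity footprint.
#' @return Numeric matrix of distances in pixels (0 on invalid pixels).
#' @export
border_distance <- function(mask) {
  stopifnot(is.matrix(mask), any(mask))
  if (all(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as_mat(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"))
}

#' Sigmoid blending weight
#'
#' The distance-based weighting function used when mosaicking:
#' `w = 1 - (d_max - d_border) / d_max` (clamped to `[0, 1]`),
#' `sig(x) = 1 / (1 + exp(-(2 x - 1) / 0.2))`, and
#' `f = (sig(w) - sig(0)) / (sig(1) - sig(0))`.
#' `f` rises monotonically from 0 at the border to 1 at `d_border >= d_max`,
#' with `f(d_max / 2) = 0.5` by the sigmoid's symmetry.
#'
#' @param d_border Distance(s) to the tile border in pixels (`>= 0`).
#' @param d_max Gradient length in pixels (`> 0`).
#' @return Weights in `[0, 1]`, same shape as `d_border`.
#' @export
blend_weight <- function(d_border, d_max) {
  if (length(d_max) != 1 || !is.finite(d_max) || d_max <= 0)
    stop("d_max must be a single positive number, got ", d_max)
  w <- pmin(pmax(d_border / d_max, 0), 1)
  sig <- function(x) 1 / (1 + exp(-(2 * x - 1) / 0.2))
  out <- (sig(w) - sig(0)) / (sig(1) - sig(0))
  out[!is.finite(d_border) & d_border > 0] <- 1
  out
}

tile_weights <- function(tiles, d_max) {
  lapply(tiles, function(t) {
    f <- matrix(0, nrow(t$mask), ncol(t$mask))
    f[t$mask] <- blend_weight(border_distance(t$mask)[t$mask], d_max)
    f
  })
}

#' Blend aligned tiles into a mosaic
#'
#' Distance-weighted combination of tile values.  In `"normalized"` mode
#' (default) the mosaic is the weighted mean
#' `sum(f_t * p_t) / sum(f_t)`, which preserves constant fields in overlaps;
#' `"as_printed"` is the literal unnormalized weighted sum.  Pixels covered
#' only by zero-weight border pixels fall back to the unweighted mean of the
#' covering tiles, so coverage never develops holes.
#'
#' @param tiles List of [tile_record()]s sharing the reference frame.
#' @param d_max Blend gradient length in pixels; default 15% of the shorter
#'   frame side.
#' @param mode `"normalized"` or `"as_printed"`.
#' @return List with `image` (mosaic matrix, `NA` outside coverage) and
#'   `mask` (logical coverage = union of tile footprints).
#' @export
blend_tiles <- function(tiles, d_max = NULL, mode = c("normalized", "as_printed")) {
  mode <- match.arg(mode)
  if (length(tiles) == 0) stop("blend_tiles needs at least one tile")
  d <- dim(tiles[[1]]$image)
  stopifnot(all(vapply(tiles, function(t) all(dim(t$image) == d), TRUE)))
  if (is.null(d_max)) d_max <- max(1, round(0.15 * min(d)))
  fs <- tile_weights(tiles, d_max)
  acc <- matrix(0, d[1], d[2]); wsum <- matrix(0, d[1], d[2])
  msum <- matrix(0, d[1], d[2]); nmask <- matrix(0, d[1], d[2])
  cover <- matrix(FALSE, d[1], d[2])
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]; f <- fs[[i]]
    p <- t$image; p[!t$mask] <- 0
    acc <- acc + f * p
    wsum <- wsum + f
    msum <- msum + p * t$mask
    nmask <- nmask + t$mask
    cover <- cover | t$mask
  }
  out <- matrix(NA_real_, d[1], d[2])
  if (mode == "normalized") {
    pos <- wsum > 0
    out[pos] <- acc[pos] / wsum[pos]
  } else {
    out[wsum > 0] <- acc[wsum > 0]
  }
  ## border-only coverage: Eq. weights all zero, use the plain mean
  zero <- cover & wsum <= 0
  out[zero] <- msum[zero] / nmask[zero]
  list(image = out, mask = cover)
}

#' Blend azimuth (orientation) tiles
#'
#' Orientation is 180-degree periodic, so the weighted combination is done on
#' doubled-angle unit vectors `(cos 2 theta, sin 2 theta)`; the blended
#' azimuth is half the angle of the summed vector, in `[0, 180)`.  Pixels
#' where the contributions cancel (resultant near zero) have no defined
#' orientation and are masked.
#'
#' @inheritParams blend_tiles
#' @return List with `image` (degrees, `NA` where undefined or uncovered)
#'   and `mask`.
#' @export
blend_azimuth <- function(tiles, d_max = NULL) {
  if (length(tiles) == 0) stop("blend_azimuth needs at least one tile")
  d <- dim(tiles[[1]]$image)
  if (is.null(d_max)) d_max <- max(1, round(0.15 * min(d)))
  fs <- tile_weights(tiles, d_max)
  cs <- matrix(0, d[1], d[2]); sn <- matrix(0, d[1], d[2])
  csm <- matrix(0, d[1], d[2]); snm <- matrix(0, d[1], d[2])
  wsum <- matrix(0, d[1], d[2]); cover <- matrix(FALSE, d[1], d[2])
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]; f <- fs[[i]]
    th <- t$image * pi / 90
    c2 <- cos(th); s2 <- sin(th)
    c2[!t$mask] <- 0; s2[!t$mask] <- 0
    cs <- cs + f * c2; sn <- sn + f * s2
    csm <- csm + c2 * t$mask; snm <- snm + s2 * t$mask
    wsum <- wsum + f
    cover <- cover | t$mask
  }
  zero <- cover & wsum <= 0
  cs[zero] <- csm[zero]; sn[zero] <- snm[zero]
  out <- matrix(NA_real_, d[1], d[2])
  res <- sqrt(cs^2 + sn^2)
  ok <- cover & res >= 1e-12
  out[ok] <- (0.5 * atan2(sn[ok], cs[ok]) * 180 / pi) %% 180
  out[ok][abs(out[ok] - 180) < 1e-9] <- 0
  list(image = out, mask = ok)
}
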