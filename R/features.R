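## Classic keypoint pipeline: difference-of-Gaussians scale-space extrema
## with subpixel refinement, dominant-orientation assignment, 4x4x8
## gradient-histogram descriptors, and mutual-nearest-neighbour matching
## with a ratio test.  Deterministic throughout; any external matcher that
## produces a match table in the same shape can be evaluated with
## evaluate_matches().

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as_mat(EBImage::gblur(img, sigma = sigma,
                         radius = 2 * ceiling(3.5 * sigma) + 1))
}

## 3-D local extrema of a DoG triplet, away from a border margin.
dog_extrema <- function(Dm, Dc, Dp, thr, margin) {
  h <- nrow(Dc); w <- ncol(Dc)
  cand <- which(abs(Dc) > thr)
  if (length(cand) == 0) return(integer(0))
  rr <- (cand - 1) %% h + 1; cc <- (cand - 1) %/% h + 1
  keep <- rr > margin & rr <= h - margin & cc > margin & cc <= w - margin
  cand <- cand[keep]; rr <- rr[keep]; cc <- cc[keep]
  if (length(cand) == 0) return(integer(0))
  v <- Dc[cand]
  ismax <- rep(TRUE, length(cand)); ismin <- rep(TRUE, length(cand))
  for (dr in -1:1) for (dc in -1:1) {
    nb <- cbind(rr + dr, cc + dc)
    for (L in list(Dm, Dc, Dp)) {
      u <- L[nb]
      if (identical(L, Dc) && dr == 0 && dc == 0) next
      ismax <- ismax & v >= u
      ismin <- ismin & v <= u
    }
  }
  cand[(ismax & v > 0) | (ismin & v < 0)]
}

#' Detect keypoints with a difference-of-Gaussians detector
#'
#' Builds a Gaussian scale-space pyramid, finds 3-D extrema of the
#' difference-of-Gaussians response, refines them to subpixel/subscale
#' accuracy with a quadratic fit, rejects low-contrast and edge-like points,
#' assigns a dominant gradient orientation, and computes an
#' orientation-normalized 4x4x8 gradient-histogram descriptor per keypoint.
#' Fully deterministic for fixed input.
#'
#' @param image Numeric matrix, at least 32 x 32.
#' @param n_octaves Maximum number of pyramid octaves.
#' @param contrast_threshold Minimum refined |DoG| response (image
#'   normalized to `[0, 1]`).
#' @param edge_ratio Principal-curvature ratio limit for the edge test.
#' @param n_scales DoG scales per octave.
#' @param sigma0 Base blur of each octave in octave pixels.
#' @return A tibble of class `keypoints` with columns `x`, `y` (0-based
#'   pixels), `scale` (the DoG sigma, input pixels), `orientation`
#'   (degrees), `response`, `octave`; descriptors (unit-norm rows) in
#'   `attr(, "descriptors")`.  Sorted by decreasing response.  A flat image
#'   yields zero rows.
#' @export
detect_keypoints <- function(image, n_octaves = 4, contrast_threshold = 0.01,
                             edge_ratio = 10, n_scales = 3, sigma0 = 1.6) {
  stopifnot(is.matrix(image), nrow(image) >= 32, ncol(image) >= 32)
  rng <- range(image, finite = TRUE)
  empty <- structure(tibble::tibble(x = numeric(0), y = numeric(0),
                                    scale = numeric(0),
                                    orientation = numeric(0),
                                    response = numeric(0),
                                    octave = integer(0)),
                     descriptors = matrix(0, 0, 128),
                     class = c("keypoints", class(tibble::tibble())))
  if (diff(rng) < .Machine$double.eps) return(empty)
  img <- (image - rng[1]) / diff(rng)
  img[!is.finite(img)] <- 0
  n_oct <- max(1, min(n_octaves, floor(log2(min(dim(img)) / 24)) + 1))
  k <- 2^(1 / n_scales)
  sig <- sigma0 * k^(0:(n_scales + 2))
  kps <- list(); descs <- list()
  base <- gaussian_blur(img, sqrt(max(sigma0^2 - 0.25, 0.01)))
  for (o in seq_len(n_oct)) {
    G <- vector("list", n_scales + 3)
    G[[1]] <- base
    for (s in 2:(n_scales + 3))
      G[[s]] <- gaussian_blur(G[[s - 1]], sqrt(sig[s]^2 - sig[s - 1]^2))
    D <- lapply(1:(n_scales + 2), function(s) G[[s + 1]] - G[[s]])
    res <- octave_keypoints(G, D, sig, o, contrast_threshold, edge_ratio,
                            n_scales)
    kps[[o]] <- res$kp; descs[[o]] <- res$desc
    if (o < n_oct) {
      nb <- G[[n_scales + 1]]
      base <- nb[seq(1, nrow(nb), by = 2), seq(1, ncol(nb), by = 2)]
      if (min(dim(base)) < 24) break
    }
  }
  kp <- do.call(rbind, kps)
  if (is.null(kp) || nrow(kp) == 0) return(empty)
  de <- do.call(rbind, descs)
  ord <- order(-kp$response)
  structure(tibble::as_tibble(kp[ord, , drop = FALSE]),
            descriptors = de[ord, , drop = FALSE],
            class = c("keypoints", class(tibble::tibble())))
}

octave_keypoints <- function(G, D, sig, octave, contrast_threshold,
                             edge_ratio, n_scales) {
  h <- nrow(D[[1]]); w <- ncol(D[[1]])
  fac <- 2^(octave - 1)
  out <- list(); dout <- list(); ct <- 0
  for (s in 2:(n_scales + 1)) {
    idx <- dog_extrema(D[[s - 1]], D[[s]], D[[s + 1]],
                       0.5 * contrast_threshold, margin = 5)
    if (length(idx) == 0) next
    rr <- (idx - 1) %% h + 1; cc <- (idx - 1) %/% h + 1
    for (t in seq_along(idx)) {
      r <- rr[t]; c <- cc[t]
      ref <- refine_extremum(D, s, r, c, contrast_threshold, edge_ratio)
      if (is.null(ref)) next
      sigma_rel <- sig[s] * 2^(ref$os / n_scales)
      ori <- keypoint_orientation(G[[s]], r + ref$oy, c + ref$ox, sigma_rel)
      dsc <- keypoint_descriptor(G[[s]], r + ref$oy, c + ref$ox, sigma_rel, ori)
      if (is.null(dsc)) next
      ct <- ct + 1
      out[[ct]] <- data.frame(
        x = (c - 1 + ref$ox) * fac, y = (r - 1 + ref$oy) * fac,
        scale = sigma_rel * fac, orientation = ori,
        response = abs(ref$val), octave = octave)
      dout[[ct]] <- dsc
    }
  }
  list(kp = if (ct) do.call(rbind, out) else NULL,
       desc = if (ct) do.call(rbind, dout) else NULL)
}

refine_extremum <- function(D, s, r, c, contrast_threshold, edge_ratio) {
  Dm <- D[[s - 1]]; Dc <- D[[s]]; Dp <- D[[s + 1]]
  g <- c((Dc[r, c + 1] - Dc[r, c - 1]) / 2,
         (Dc[r + 1, c] - Dc[r - 1, c]) / 2,
         (Dp[r, c] - Dm[r, c]) / 2)
  dxx <- Dc[r, c + 1] + Dc[r, c - 1] - 2 * Dc[r, c]
  dyy <- Dc[r + 1, c] + Dc[r - 1, c] - 2 * Dc[r, c]
  dss <- Dp[r, c] + Dm[r, c] - 2 * Dc[r, c]
  dxy <- (Dc[r + 1, c + 1] - Dc[r + 1, c - 1] -
          Dc[r - 1, c + 1] + Dc[r - 1, c - 1]) / 4
  dxs <- (Dp[r, c + 1] - Dp[r, c - 1] - Dm[r, c + 1] + Dm[r, c - 1]) / 4
  dys <- (Dp[r + 1, c] - Dp[r - 1, c] - Dm[r + 1, c] + Dm[r - 1, c]) / 4
  H <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3)
  off <- tryCatch(-solve(H, g), error = function(e) NULL)
  if (is.null(off) || any(!is.finite(off)) || max(abs(off)) > 1.5) return(NULL)
  val <- Dc[r, c] + sum(g * off) / 2
  if (abs(val) < contrast_threshold) return(NULL)
  tr <- dxx + dyy; det2 <- dxx * dyy - dxy^2
  if (det2 <= 0 || tr^2 / det2 >= (edge_ratio + 1)^2 / edge_ratio) return(NULL)
  list(ox = off[1], oy = off[2], os = off[3], val = val)
}

## Gradients of a Gaussian level at fractional positions (central diffs on
## the integer grid, bilinear between).
grad_at <- function(Gs, x, y) {
  gx <- sample_image(Gs, x + 1, y) - sample_image(Gs, x - 1, y)
  gy <- sample_image(Gs, x, y + 1) - sample_image(Gs, x, y - 1)
  list(gx = gx / 2, gy = gy / 2)
}

keypoint_orientation <- function(Gs, r, c, sigma_rel) {
  x0 <- c - 1; y0 <- r - 1
  rad <- max(3L, ceiling(3 * 1.5 * sigma_rel))
  off <- -rad:rad
  dx <- rep(off, times = length(off)); dy <- rep(off, each = length(off))
  g <- grad_at(Gs, x0 + dx, y0 + dy)
  mag <- sqrt(g$gx^2 + g$gy^2)
  wgt <- exp(-(dx^2 + dy^2) / (2 * (1.5 * sigma_rel)^2))
  ok <- !is.na(mag) & mag > 0
  if (!any(ok)) return(0)
  ang <- (atan2(g$gy[ok], g$gx[ok]) * 180 / pi) %% 360
  hist <- rep(0, 36)
  bin <- floor(ang / 10) %% 36 + 1
  for (i in seq_along(bin))
    hist[bin[i]] <- hist[bin[i]] + mag[ok][i] * wgt[ok][i]
  ## circular smoothing
  for (pass in 1:2)
    hist <- (hist + c(hist[-1], hist[1]) + c(hist[36], hist[-36])) / 3
  b <- which.max(hist)
  l <- hist[if (b == 1) 36 else b - 1]; rr <- hist[if (b == 36) 1 else b + 1]
  den <- l - 2 * hist[b] + rr
  shift <- if (abs(den) > 1e-12) 0.5 * (l - rr) / den else 0
  ((b - 1 + shift) * 10) %% 360
}

keypoint_descriptor <- function(Gs, r, c, sigma_rel, orientation,
                                n_cells = 4, n_ori = 8) {
  x0 <- c - 1; y0 <- r - 1
  spacing <- 0.75 * sigma_rel
  n_samp <- 4 * n_cells          # 16 x 16 sample grid
  off <- (seq_len(n_samp) - (n_samp + 1) / 2)
  du <- rep(off, times = n_samp) * spacing
  dv <- rep(off, each = n_samp) * spacing
  th <- orientation * pi / 180
  ct <- cos(th); st <- sin(th)
  px <- x0 + ct * du - st * dv
  py <- y0 + st * du + ct * dv
  g <- grad_at(Gs, px, py)
  if (all(is.na(g$gx))) return(NULL)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mag[is.na(mag)] <- 0
  wgt <- exp(-(du^2 + dv^2) / (2 * (spacing * n_samp / 2)^2))
  ang <- ((atan2(g$gy, g$gx) * 180 / pi) - orientation) %% 360
  ang[is.na(ang)] <- 0
  ## soft-binned accumulation: bilinear over 4x4 cells, linear over 8 bins
  ci <- (rep(seq_len(n_samp), times = n_samp) - 0.5) / 4 - 0.5
  cj <- (rep(seq_len(n_samp), each = n_samp) - 0.5) / 4 - 0.5
  ob <- ang / (360 / n_ori)
  desc <- array(0, dim = c(n_cells, n_cells, n_ori))
  wm <- mag * wgt
  for (ii in 0:1) for (jj in 0:1) for (oo in 0:1) {
    bi <- floor(ci) + ii; bj <- floor(cj) + jj
    bo <- (floor(ob) + oo) %% n_ori
    wt <- (1 - abs(ci - bi)) * (1 - abs(cj - bj)) *
      (1 - abs(ob - (floor(ob) + oo)))
    sel <- bi >= 0 & bi < n_cells & bj >= 0 & bj < n_cells & wt > 0
    if (!any(sel)) next
    idx <- bi[sel] + n_cells * bj[sel] + n_cells * n_cells * bo[sel] + 1
    acc <- rowsum(wm[sel] * wt[sel], idx)
    desc[as.integer(rownames(acc))] <- desc[as.integer(rownames(acc))] + acc
  }
  v <- as.vector(desc)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(NULL)
  v <- pmin(v / nrm, 0.2)
  v / sqrt(sum(v^2))
}

#' Subset a keypoint set
#'
#' Row-subsets a `keypoints` tibble while keeping the descriptor matrix in
#' step (plain `[` would drop it).
#'
#' @param kp A `keypoints` object.
#' @param keep Logical or integer index vector.
#' @return The filtered `keypoints` object.
#' @export
filter_keypoints <- function(kp, keep) {
  structure(tibble::as_tibble(as.data.frame(kp)[keep, , drop = FALSE]),
            descriptors = attr(kp, "descriptors")[keep, , drop = FALSE],
            class = class(kp))
}

#' Mutual-nearest-neighbour descriptor matching with ratio test
#'
#' Matches descriptor sets by nearest neighbour in descriptor space, keeping
#' a pair only if (a) the nearest/second-nearest distance ratio on the
#' fixed-to-moving side is at most `ratio` (Lowe's ratio test) and (b) the
#' two keypoints are each other's nearest neighbours (mutual check).  The
#' result is one-to-one.
#'
#' @param fixed,moving `keypoints` objects from [detect_keypoints()] (or any
#'   tibble with `x`, `y` and a `descriptors` attribute).
#' @param ratio Ratio-test cutoff in `(0, 1]`.
#' @return A tibble of class `match_set` with columns `x_fixed`, `y_fixed`,
#'   `x_moving`, `y_moving`, `score` (descriptor distance).
#' @export
match_mnn <- function(fixed, moving, ratio = 0.75) {
  stopifnot(ratio > 0, ratio <= 1)
  empty <- structure(tibble::tibble(x_fixed = numeric(0), y_fixed = numeric(0),
                                    x_moving = numeric(0),
                                    y_moving = numeric(0), score = numeric(0)),
                     class = c("match_set", class(tibble::tibble())))
  Df <- attr(fixed, "descriptors"); Dm <- attr(moving, "descriptors")
  if (is.null(Df) || is.null(Dm) || nrow(Df) == 0 || nrow(Dm) == 0)
    return(empty)
  stopifnot(ncol(Df) == ncol(Dm))
  d2 <- pmax(2 - 2 * Df %*% t(Dm), 0)      # unit-norm descriptors
  nn1 <- max.col(-d2, ties.method = "first")
  keep <- logical(nrow(d2))
  for (i in seq_len(nrow(d2))) {
    di <- sqrt(d2[i, ])
    o <- nn1[i]
    d1 <- di[o]
    d2nd <- if (length(di) > 1) min(di[-o]) else Inf
    keep[i] <- d1 <= ratio * d2nd
  }
  rev_nn <- apply(d2, 2, which.min)
  mutual <- keep & rev_nn[nn1] == seq_len(nrow(d2))
  if (!any(mutual)) return(empty)
  i <- which(mutual); j <- nn1[mutual]
  structure(tibble::tibble(x_fixed = fixed$x[i], y_fixed = fixed$y[i],
                           x_moving = moving$x[j], y_moving = moving$y[j],
                           score = sqrt(d2[cbind(i, j)])),
            class = c("match_set", class(tibble::tibble())))
}

#' Evaluate matches against a ground-truth deformation
#'
#' Maps each fixed keypoint through the ground-truth deformation field into
#' the moving frame, measures the Euclidean distance to the predicted moving
#' keypoint, and summarizes: RMSE (`sqrt(mean(d^2))`), precision (percentage
#' of matches with distance strictly below `threshold`), and counts in
#' good / moderate / outlier distance bands.  Fixed points outside the
#' ground-truth domain are excluded from the statistics and reported in
#' `dropped`.
#'
#' @param matches A `match_set` (or data frame with the same columns).
#' @param gt A [deformation_field()] from the fixed to the moving frame.
#' @param threshold True-positive distance threshold in pixels (strict
#'   "less than"); 15 for reference-photo-scale alignments, 5 for
#'   histology-pair-scale.
#' @param bands `c(b1, b2)`: band edges, good `d < b1`, moderate
#'   `b1 <= d < b2`, outlier `d >= b2`.
#' @param pixel_pitch Optional mm per pixel; adds `rmse_mm`.
#' @return Object of class `match_evaluation`.
#' @export
evaluate_matches <- function(matches, gt, threshold = 15, bands = c(15, 50),
                             pixel_pitch = NULL) {
  stopifnot(nrow(matches) > 0, length(bands) == 2, bands[1] <= bands[2])
  mp <- map_points(gt, data.frame(x = matches$x_fixed, y = matches$y_fixed))
  ok <- mp$in_domain
  if (!any(ok))
    stop("no matches inside the ground-truth domain; cannot evaluate")
  d <- sqrt((mp$x[ok] - matches$x_moving[ok])^2 +
            (mp$y[ok] - matches$y_moving[ok])^2)
  n <- length(d)
  rmse <- sqrt(mean(d^2))
  structure(list(
    distances = d, n = n, dropped = sum(!ok),
    rmse_px = rmse,
    rmse_mm = if (is.null(pixel_pitch)) NA_real_ else rmse * pixel_pitch,
    precision_pct = 100 * sum(d < threshold) / n,
    threshold_px = threshold, bands = bands,
    band_counts = c(good = sum(d < bands[1]),
                    moderate = sum(d >= bands[1] & d < bands[2]),
                    outlier = sum(d >= bands[2]))),
    class = "match_evaluation")
}

#' @export
print.match_evaluation <- function(x, ...) {
  cat(sprintf("<match_evaluation> n = %d (dropped %d)\n", x$n, x$dropped))
  cat(sprintf("  RMSE %.3f px%s | precision %.2f%% at < %g px\n",
              x$rmse_px,
              if (is.na(x$rmse_mm)) "" else sprintf(" (%.3f mm)", x$rmse_mm),
              x$precision_pct, x$threshold_px))
  cat(sprintf("  bands: good %d, moderate %d, outlier %d\n",
              x$band_counts["good"], x$band_counts["moderate"],
              x$band_counts["outlier"]))
  invisible(x)
}
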