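## Synthetic brain-section phantom: a reference "photograph" with gray/white
## matter (GM/WM) classes, a per-pixel Mueller-matrix field built from known
## polarimetric parameters, overlapping polarimetric tiles under small rigid
## perturbations, and disjoint "histology" fragments under known rigid +
## elastic deformations.  Every product carries an exact ground-truth
## deformation, so matching, warping, blending and label reconstruction are
## all testable without external data.

#' Generate a brain-section-like phantom scene
#'
#' Builds a tissue silhouette (perturbed ellipse on a dark background) split
#' into connected GM and WM regions, a band-limited textured reference image,
#' smooth ground-truth parameter fields (depolarization, linear retardance,
#' azimuth), and the corresponding per-pixel Mueller-matrix field
#' `intensity * depolarizer(1 - Delta) %*% linear_retarder(theta, delta)`.
#' WM depolarization is drawn in `delta_wm` (above the 0.88 quiver-mask
#' threshold) and GM in `delta_gm` (below it), so depolarization-based
#' masking separates the classes by construction.
#'
#' @param width,height Scene size in pixels (each `>= 64`).
#' @param texture_scale Correlation length of the image texture in pixels;
#'   controls the blob size available to keypoint detectors.
#' @param seed Integer; fixes all randomness.
#' @param pixel_pitch mm per pixel of the reference frame (default 0.029).
#' @param delta_gm,delta_wm Depolarization ranges for GM and WM.
#' @param ret_gm,ret_wm Linear-retardance ranges (degrees) for GM and WM.
#' @return Object of class `phantom_scene`: `reference_image` (`[0, 1]`),
#'   `labels` (0 = background, 1 = GM, 2 = WM), `mueller`
#'   (a [mueller_image()]), `params` (list of ground-truth maps `intensity`,
#'   `depolarization`, `linear_retardance`, `azimuth`), `pixel_pitch`.
#' @export
generate_phantom <- function(width, height, texture_scale = 16, seed = 1,
                             pixel_pitch = 0.029,
                             delta_gm = c(0.80, 0.87),
                             delta_wm = c(0.92, 0.98),
                             ret_gm = c(2, 12), ret_wm = c(25, 60)) {
  if (width < 64 || height < 64)
    stop("phantom must be at least 64 x 64 to contain both tissue classes")
  with_seed(seed, {
    h <- height; w <- width
    gx <- grid_x(h, w); gy <- grid_y(h, w)
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    phi <- atan2(gy - cy, gx - cx)
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    wig <- 1 + 0.06 * sin(2 * phi + ph1) + 0.05 * sin(3 * phi + ph2)
    rr <- ((gx - cx) / (0.44 * w))^2 + ((gy - cy) / (0.44 * h))^2
    tissue <- rr <= wig^2
    ## WM: thresholded smooth field over the tissue, lightly cleaned
    s1 <- smooth_noise(h, w, sigma = min(h, w) / 10)
    thr <- stats::quantile(s1[tissue], 0.6)
    wm <- tissue & s1 > thr
    br <- EBImage::makeBrush(5, "disc")
    wm <- as_mat(EBImage::opening(EBImage::Image(wm * 1), br)) > 0.5
    wm <- wm & tissue
    labels <- matrix(0L, h, w)
    labels[tissue] <- 1L
    labels[wm] <- 2L
    ## reference image: class-dependent mean + band-limited texture
    tex <- 2 * smooth_noise(h, w, sigma = texture_scale / 4) - 1
    tex2 <- 2 * smooth_noise(h, w, sigma = max(1, texture_scale / 8)) - 1
    base <- 0.08 + 0.37 * (labels == 1L) + 0.70 * (labels == 2L)
    ref <- pmin(pmax(base + 0.12 * tex + 0.06 * tex2, 0), 1)
    ## smooth ground-truth parameter fields
    u <- smooth_noise(h, w, sigma = min(h, w) / 12)
    v <- smooth_noise(h, w, sigma = min(h, w) / 12)
    depol <- matrix(0.30, h, w)
    depol[labels == 1L] <- delta_gm[1] + diff(delta_gm) * u[labels == 1L]
    depol[labels == 2L] <- delta_wm[1] + diff(delta_wm) * u[labels == 2L]
    ret <- matrix(0, h, w)
    ret[labels == 1L] <- ret_gm[1] + diff(ret_gm) * v[labels == 1L]
    ret[labels == 2L] <- ret_wm[1] + diff(ret_wm) * v[labels == 2L]
    oc <- 2 * smooth_noise(h, w, sigma = min(h, w) / 10) - 1
    os <- 2 * smooth_noise(h, w, sigma = min(h, w) / 10) - 1
    azim <- (0.5 * atan2(os, oc) * 180 / pi) %% 180
    azim[labels == 0L] <- 0
    ret[labels == 0L] <- 0
    azim[ret == 0] <- 0   # orientation undefined without retardance
    intensity <- pmax(ref, 0.02)
    mm <- mueller_field(intensity, depol, ret, azim)
    structure(list(reference_image = ref, labels = labels,
                   mueller = mm,
                   params = list(intensity = intensity,
                                 depolarization = depol,
                                 linear_retardance = ret,
                                 azimuth = azim),
                   pixel_pitch = pixel_pitch, seed = seed),
              class = "phantom_scene")
  })
}

## Vectorized forward model: per-pixel
## intensity * diag(1, a, a, a) %*% linear_retarder(theta, delta), a = 1 - Delta.
## Channel order row-major m00..m33.
mueller_field <- function(intensity, depol, ret, azim) {
  h <- nrow(intensity); w <- ncol(intensity)
  a <- 1 - depol
  c2 <- cos(2 * azim * pi / 180); s2 <- sin(2 * azim * pi / 180)
  cd <- cos(ret * pi / 180); sd <- sin(ret * pi / 180)
  m <- array(0, dim = c(h, w, 16))
  m[, , 1] <- intensity
  ai <- a * intensity
  m[, , 6]  <- ai * (c2^2 + s2^2 * cd)
  m[, , 7]  <- ai * (c2 * s2 * (1 - cd))
  m[, , 8]  <- ai * (-s2 * sd)
  m[, , 10] <- ai * (s2 * c2 * (1 - cd))
  m[, , 11] <- ai * (s2^2 + c2^2 * cd)
  m[, , 12] <- ai * (c2 * sd)
  m[, , 14] <- ai * (s2 * sd)
  m[, , 15] <- ai * (-c2 * sd)
  m[, , 16] <- ai * cd
  mueller_image(m)
}

## Sample every phantom channel through a forward rigid/elastic map.
## fx, fy: reference-frame coordinates for each pixel of the output frame.
sample_scene_channels <- function(scene, fx, fy, dims, gain = 1, offset = 0) {
  sampled <- function(img, method = "bilinear")
    matrix(sample_image(img, fx, fy, method = method), dims[1], dims[2])
  inten <- sampled(scene$reference_image)
  mask <- !is.na(inten)
  ## azimuth through doubled-angle components (orientation-safe interpolation)
  th <- scene$params$azimuth * pi / 90
  ac <- sampled(cos(th)); as_ <- sampled(sin(th))
  az <- (0.5 * atan2(as_, ac) * 180 / pi) %% 180
  list(channels = list(
         intensity = pmin(pmax(gain * inten + offset, 0), 1),
         depolarization = sampled(scene$params$depolarization),
         linear_retardance = sampled(scene$params$linear_retardance),
         azimuth = az,
         labels = sampled(matrix(as.numeric(scene$labels),
                                 nrow(scene$labels)), method = "nearest")),
       mask = mask)
}

#' Extract overlapping polarimetric tiles from a phantom scene
#'
#' Cuts the scene into a raster grid of tiles with the given fractional
#' overlap, resampling each through a small random rigid perturbation
#' (translation up to `jitter_px`, rotation up to `jitter_deg` about the tile
#' center) and a per-tile photometric gain/offset jitter.  Each tile comes
#' with its exact ground-truth backward map (reference frame to tile frame).
#'
#' @param scene A [generate_phantom()] scene.
#' @param tile_w,tile_h Tile size in pixels.
#' @param overlap_frac Fractional overlap between adjacent tiles
#'   (`0 <= overlap_frac < 0.5`; the acquisition protocol's nominal value is
#'   0.15).
#' @param jitter_px,jitter_deg Maximum rigid perturbation.
#' @param seed Integer seed.
#' @param gain_jitter,offset_jitter Photometric jitter half-ranges applied to
#'   the intensity channel.
#' @return List of phantom tiles, each a list with `channels` (intensity,
#'   depolarization, linear_retardance, azimuth, labels), `mask`, `tile_id`,
#'   `origin` (nominal 0-based placement), `rigid` (`dx, dy, degrees`), and
#'   `gt` (a full-frame [deformation_field()], reference -> tile).
#' @export
extract_polarimetric_tiles <- function(scene, tile_w, tile_h,
                                       overlap_frac = 0.15,
                                       jitter_px = 0, jitter_deg = 0,
                                       seed = 1,
                                       gain_jitter = 0.1,
                                       offset_jitter = 0.02) {
  h <- nrow(scene$reference_image); w <- ncol(scene$reference_image)
  if (overlap_frac < 0 || overlap_frac >= 0.5)
    stop("overlap_frac must be in [0, 0.5), got ", overlap_frac)
  stride_x <- tile_w - round(overlap_frac * tile_w)
  stride_y <- tile_h - round(overlap_frac * tile_h)
  if (stride_x < 1 || stride_y < 1)
    stop("overlap so large that the tile grid degenerates")
  xs <- seq(0, max(0, w - tile_w), by = stride_x)
  ys <- seq(0, max(0, h - tile_h), by = stride_y)
  if (xs[length(xs)] + tile_w < w) xs <- c(xs, w - tile_w)
  if (ys[length(ys)] + tile_h < h) ys <- c(ys, h - tile_h)
  ct <- c((tile_w - 1) / 2, (tile_h - 1) / 2)
  ux <- as.vector(grid_x(tile_h, tile_w)); uy <- as.vector(grid_y(tile_h, tile_w))
  gxf <- as.vector(grid_x(h, w)); gyf <- as.vector(grid_y(h, w))
  with_seed(seed, {
    tiles <- list(); id <- 0L
    for (y0 in ys) for (x0 in xs) {
      id <- id + 1L
      dx <- stats::runif(1, -jitter_px, jitter_px)
      dy <- stats::runif(1, -jitter_px, jitter_px)
      ang <- stats::runif(1, -jitter_deg, jitter_deg)
      gain <- 1 + stats::runif(1, -gain_jitter, gain_jitter)
      off <- stats::runif(1, -offset_jitter, offset_jitter)
      fwd <- rigid_map(x0 + dx, y0 + dy, ang, pivot = ct)
      P <- fwd(ux, uy)
      smp <- sample_scene_channels(scene, P$x, P$y, c(tile_h, tile_w),
                                   gain = gain, offset = off)
      inv <- rigid_inverse(x0 + dx, y0 + dy, ang, pivot = ct)
      Q <- inv(gxf, gyf)
      inb <- Q$x >= 0 & Q$x <= tile_w - 1 & Q$y >= 0 & Q$y <= tile_h - 1
      gt <- deformation_field(matrix(ifelse(inb, Q$x, NA_real_), h, w),
                              matrix(ifelse(inb, Q$y, NA_real_), h, w))
      tiles[[id]] <- list(channels = smp$channels, mask = smp$mask,
                          tile_id = id, origin = c(x0, y0),
                          rigid = c(dx = dx, dy = dy, deg = ang),
                          gain = gain, offset = off, gt = gt)
    }
    tiles
  })
}

## Band-limited per-axis displacement field with max |u| = amp.
elastic_displacement <- function(h, w, amp, scale) {
  if (amp <= 0) return(list(ex = matrix(0, h, w), ey = matrix(0, h, w)))
  ex <- 2 * smooth_noise(h, w, sigma = scale / 4) - 1
  ey <- 2 * smooth_noise(h, w, sigma = scale / 4) - 1
  mx <- max(abs(ex), abs(ey))
  list(ex = ex * amp / mx, ey = ey * amp / mx)
}

#' Fragment a phantom scene into disjoint "histology" tiles
#'
#' Cuts the scene into a cassette grid with `gap_px` pixels of tissue lost at
#' each internal cut line (no overlap between fragments, mirroring physically
#' cut histological sections), then deforms each fragment by a random rigid
#' transformation plus a smooth elastic displacement field with amplitude
#' `elastic_amp` and correlation length `elastic_scale`.  The exact backward
#' ground-truth map (reference -> fragment frame) is returned per fragment.
#'
#' @param scene A [generate_phantom()] scene.
#' @param cassette_w,cassette_h Cassette cell size in pixels.
#' @param gap_px Tissue lost at each internal cut line (`>= 0`).
#' @param rigid_max `c(px, degrees)`: maximum rigid perturbation.
#' @param elastic_amp,elastic_scale Elastic amplitude and correlation length
#'   in pixels; `elastic_amp` must be `< elastic_scale / 2` (folding guard).
#' @param seed Integer seed.
#' @param gain_jitter Photometric gain jitter half-range.
#' @return List of fragments with `channels` (image, labels), `mask`
#'   (fragment frame), `source_mask` (reference-frame footprint), `gt`
#'   (full-frame [deformation_field()]), `tile_id`.
#' @export
fragment_histology <- function(scene, cassette_w, cassette_h, gap_px = 0,
                               rigid_max = c(0, 0), elastic_amp = 0,
                               elastic_scale = 64, seed = 1,
                               gain_jitter = 0.1) {
  if (gap_px < 0) stop("gap_px must be >= 0")
  if (elastic_amp > 0 && elastic_amp >= elastic_scale / 2)
    stop("elastic_amp must be < elastic_scale / 2 to preclude folding")
  h <- nrow(scene$reference_image); w <- ncol(scene$reference_image)
  nx <- ceiling(w / cassette_w); ny <- ceiling(h / cassette_h)
  margin <- ceiling(rigid_max[1] + elastic_amp +
                    sin(abs(rigid_max[2]) * pi / 180) *
                      max(cassette_w, cassette_h) / 2) + 2
  with_seed(seed, {
    frags <- list(); id <- 0L
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      id <- id + 1L
      xlo <- (i - 1) * cassette_w; xhi <- min(i * cassette_w, w) - 1
      ylo <- (j - 1) * cassette_h; yhi <- min(j * cassette_h, h) - 1
      ## trim gap halves on internal edges only
      sxlo <- xlo + if (i > 1) ceiling(gap_px / 2) else 0
      sxhi <- xhi - if (i < nx) floor(gap_px / 2) else 0
      sylo <- ylo + if (j > 1) ceiling(gap_px / 2) else 0
      syhi <- yhi - if (j < ny) floor(gap_px / 2) else 0
      dx <- stats::runif(1, -rigid_max[1], rigid_max[1])
      dy <- stats::runif(1, -rigid_max[1], rigid_max[1])
      ang <- stats::runif(1, -rigid_max[2], rigid_max[2])
      gain <- 1 + stats::runif(1, -gain_jitter, gain_jitter)
      fw <- xhi - xlo + 1 + 2 * margin
      fh <- yhi - ylo + 1 + 2 * margin
      E <- elastic_displacement(fh, fw, elastic_amp, elastic_scale)
      cf <- c((fw - 1) / 2, (fh - 1) / 2)
      base <- c(xlo - margin, ylo - margin)
      rig <- rigid_map(base[1] + dx, base[2] + dy, ang, pivot = cf)
      ux <- as.vector(grid_x(fh, fw)); uy <- as.vector(grid_y(fh, fw))
      P <- rig(ux, uy)
      Px <- P$x + as.vector(E$ex); Py <- P$y + as.vector(E$ey)
      smp <- sample_scene_channels(scene, Px, Py, c(fh, fw), gain = gain)
      in_src <- Px >= sxlo - 0.5 & Px < sxhi + 0.5 &
                Py >= sylo - 0.5 & Py < syhi + 0.5
      mask <- smp$mask & matrix(in_src, fh, fw)
      ## reference-frame footprint: exactly the source rectangle
      src <- matrix(FALSE, h, w)
      if (sxhi >= sxlo && syhi >= sylo)
        src[(sylo:syhi) + 1, (sxlo:sxhi) + 1] <- TRUE
      gt <- invert_fragment_map(src, rig_inv = rigid_inverse(
              base[1] + dx, base[2] + dy, ang, pivot = cf), E = E)
      frags[[id]] <- list(channels = smp$channels[c("intensity", "labels")],
                          mask = mask, source_mask = src, gt = gt,
                          tile_id = id, rigid = c(dx = dx, dy = dy, deg = ang))
    }
    frags
  })
}

## Invert u -> rig(u) + E(u) on the reference-frame pixels marked in src.
invert_fragment_map <- function(src, rig_inv, E, tol = 0.01, max_iter = 50) {
  h <- nrow(src); w <- ncol(src)
  xm <- matrix(NA_real_, h, w); ym <- matrix(NA_real_, h, w)
  idx <- which(src)
  if (length(idx) > 0) {
    X <- (col(src)[idx]) - 1; Y <- (row(src)[idx]) - 1
    v <- rig_inv(X, Y)
    vx <- v$x; vy <- v$y
    for (k in seq_len(max_iter)) {
      ex <- sample_image(E$ex, vx, vy, fill = 0)
      ey <- sample_image(E$ey, vx, vy, fill = 0)
      nv <- rig_inv(X - ex, Y - ey)
      step <- max(abs(nv$x - vx), abs(nv$y - vy))
      vx <- nv$x; vy <- nv$y
      if (step < tol) break
    }
    xm[idx] <- vx; ym[idx] <- vy
  }
  deformation_field(xm, ym, src)
}

#' Build a fixed/moving image pair with a known deformation
#'
#' Deforms `image` through a rigid transformation (about the image center)
#' composed with a smooth elastic displacement, returning the pair together
#' with the exact ground-truth map from fixed to moving coordinates --- the
#' construction used to benchmark keypoint matchers on histology-style
#' pairs.
#'
#' @param image Numeric matrix (the fixed image).
#' @param rigid `c(dx, dy, degrees)`.
#' @param elastic_amp,elastic_scale Elastic displacement amplitude and
#'   correlation length (pixels).
#' @param seed Integer seed.
#' @param fill Background fill for unobserved moving pixels.
#' @return List with `fixed`, `moving`, `moving_mask`, and `gt`
#'   (a [deformation_field()] over the fixed frame).
#' @export
make_pair <- function(image, rigid = c(0, 0, 0), elastic_amp = 0,
                      elastic_scale = 32, seed = 1, fill = 0) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (elastic_amp > 0 && elastic_amp >= elastic_scale / 2)
    stop("elastic_amp must be < elastic_scale / 2 to preclude folding")
  h <- nrow(image); w <- ncol(image)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  with_seed(seed, {
    E <- elastic_displacement(h, w, elastic_amp, elastic_scale)
    fwd <- rigid_map(rigid[1], rigid[2], rigid[3], pivot = ctr)
    inv <- rigid_inverse(rigid[1], rigid[2], rigid[3], pivot = ctr)
    gx <- grid_x(h, w); gy <- grid_y(h, w)
    G <- fwd(as.vector(gx), as.vector(gy))
    gt <- deformation_field(matrix(G$x + as.vector(E$ex), h, w),
                            matrix(G$y + as.vector(E$ey), h, w))
    ## moving(u) = fixed(G^{-1}(u)): solve v = inv(u - E(v))
    ux <- as.vector(gx); uy <- as.vector(gy)
    v <- inv(ux, uy)
    vx <- v$x; vy <- v$y
    if (elastic_amp > 0) {
      for (k in 1:50) {
        ex <- sample_image(E$ex, vx, vy, fill = 0)
        ey <- sample_image(E$ey, vx, vy, fill = 0)
        nv <- inv(ux - ex, uy - ey)
        step <- max(abs(nv$x - vx), abs(nv$y - vy))
        vx <- nv$x; vy <- nv$y
        if (step < 0.01) break
      }
    }
    mv <- sample_image(image, vx, vy)
    mask <- matrix(!is.na(mv), h, w)
    moving <- matrix(ifelse(is.na(mv), fill, mv), h, w)
    list(fixed = image, moving = moving, moving_mask = mask, gt = gt)
  })
}
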