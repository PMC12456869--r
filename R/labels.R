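## Categorical label-map reconstruction: warp fragment label tiles into the
## reference frame, fill the gaps left by tissue lost at cut lines, and
## extract/dilate GM-WM border masks for validation.

#' Warp label tiles into the reference frame
#'
#' Nearest-neighbour resampling of categorical label tiles through their
#' deformation fields (labels must never be interpolated).  Fragments are
#' disjoint by construction; should footprints ever overlap, the first tile
#' wins.  Uncovered pixels are background with empty provenance.
#'
#' @param tiles List of lists, each with `labels` (integer matrix in the
#'   tile frame), `gt` (a [deformation_field()] reference -> tile), optional
#'   `mask` (tile-frame validity), and `tile_id`.
#' @param frame `c(h, w)` of the reference frame.
#' @return Object of class `label_map`: `labels` (integer matrix,
#'   0 = background), `provenance` (integer matrix, `NA` = unlabeled,
#'   `-1` = filled, otherwise tile_id).
#' @export
warp_labels <- function(tiles, frame) {
  h <- frame[1]; w <- frame[2]
  labels <- matrix(0L, h, w)
  prov <- matrix(NA_integer_, h, w)
  for (t in tiles) {
    lab <- t$labels
    if (!is.null(t$mask)) {
      lab <- lab
      lab[!t$mask] <- NA_real_
    }
    wr <- apply_warp(lab, t$gt, interpolation = "nearest")
    put <- wr$mask & is.na(prov)
    labels[put] <- as.integer(wr$image[put])
    prov[put] <- t$tile_id %||% 0L
  }
  structure(list(labels = labels, provenance = prov), class = "label_map")
}

#' Fill unlabeled gaps in a reconstructed label map
#'
#' Assigns each unlabeled pixel inside the tissue silhouette the label of
#' its nearest labeled pixel (Euclidean), restricted to gaps no wider than
#' `max_gap` (distance to the nearest label at most `max_gap`); ties between
#' classes go to WM, which reconnects WM bands split by cut lines.  A
#' morphological closing on the WM class (within the filled region only)
#' then smooths reconnection seams.  Originally labeled pixels are never
#' altered; gaps wider than `max_gap` remain unlabeled and are reported via
#' the `unfilled` attribute.
#'
#' @param partial A [warp_labels()] result.
#' @param silhouette Logical matrix: tissue region of the reference frame.
#' @param max_gap Maximum gap half-width to fill, in pixels.
#' @param classes Integer labels eligible for filling (default `c(1, 2)`).
#' @return A `label_map` with filled pixels flagged `-1` in `provenance` and
#'   an integer attribute `unfilled`.
#' @export
fill_gaps <- function(partial, silhouette, max_gap = 12, classes = c(1L, 2L)) {
  labels <- partial$labels
  prov <- partial$provenance
  gap <- silhouette & is.na(prov)
  if (!any(gap)) {
    attr(partial, "unfilled") <- 0L
    return(partial)
  }
  ## distance from every pixel to the nearest pixel of each class
  dists <- lapply(classes, function(cl) {
    src <- labels == cl & !is.na(prov)
    if (!any(src)) return(matrix(Inf, nrow(labels), ncol(labels)))
    as_mat(EBImage::distmap(EBImage::Image(1 - src * 1)))
  })
  dmin <- Reduce(pmin, dists)
  nearest <- matrix(classes[1], nrow(labels), ncol(labels))
  for (k in seq_along(classes)[-1])
    nearest[dists[[k]] <= dmin] <- classes[k]   # ties -> later class (WM)
  fillable <- gap & dmin <= max_gap
  labels[fillable] <- nearest[fillable]
  prov[fillable] <- -1L
  ## reconnect WM bands across filled seams: closing on WM, applied only to
  ## filled/background-of-gap pixels so original labels are untouched
  wm_cl <- classes[length(classes)]
  wm <- labels == wm_cl & !is.na(prov)
  sz <- 2 * max_gap + 1
  closed <- as_mat(EBImage::closing(EBImage::Image(wm * 1),
                                       EBImage::makeBrush(
                                         sz + (1 - sz %% 2), "box"))) > 0.5
  promote <- closed & fillable & labels != wm_cl
  labels[promote] <- wm_cl
  out <- structure(list(labels = labels, provenance = prov),
                   class = "label_map")
  attr(out, "unfilled") <- sum(gap & !fillable)
  out
}

#' Extract the 1-px border between two label classes
#'
#' The border mask consists of the `class_b` pixels 4-adjacent to a
#' `class_a` pixel (single-sided convention, so a straight border is exactly
#' one pixel wide).
#'
#' @param labels Integer label matrix or `label_map`.
#' @param class_a,class_b The two classes (border taken on the `class_b`
#'   side; default GM = 1, WM = 2).
#' @param width_px Nominal width recorded in the result (1 for a fresh
#'   border).
#' @param pixel_pitch mm per pixel recorded for physical-width reporting.
#' @return Object of class `border_mask`: `mask` (logical), `width_px`,
#'   `pixel_pitch`.
#' @export
extract_border <- function(labels, class_a = 1L, class_b = 2L,
                           pixel_pitch = NA_real_, width_px = 1L) {
  if (inherits(labels, "label_map")) labels <- labels$labels
  h <- nrow(labels); w <- ncol(labels)
  a <- labels == class_a; b <- labels == class_b
  if (!any(a) || !any(b)) {
    warning("class ", if (!any(a)) class_a else class_b,
            " absent; border mask is empty")
    return(structure(list(mask = matrix(FALSE, h, w), width_px = 0L,
                          pixel_pitch = pixel_pitch), class = "border_mask"))
  }
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  adj <- pad(a, 1, 0) | pad(a, -1, 0) | pad(a, 0, 1) | pad(a, 0, -1)
  structure(list(mask = b & adj, width_px = as.integer(width_px),
                 pixel_pitch = pixel_pitch), class = "border_mask")
}

#' Dilate a border mask by a kernel protocol
#'
#' Sequential morphological dilation with full-square structuring elements.
#' The default protocol --- an 11 x 11 kernel for five iterations followed by
#' a 5 x 5 kernel for one iteration --- widens a 1-px straight line to a
#' 55-px band: each pass with an odd `k x k` square adds `(k - 1) / 2`
#' pixels per side, so `1 + 2 * (5 * 5) + 2 * 2 = 55`.
#'
#' @param border A [extract_border()] result (or logical matrix).
#' @param protocol List of `c(kernel_size, iterations)` pairs; kernels must
#'   be odd.
#' @return A `border_mask` with updated `width_px`.
#' @export
dilate_border <- function(border, protocol = list(c(11, 5), c(5, 1))) {
  if (is.matrix(border) && is.logical(border))
    border <- structure(list(mask = border, width_px = 1L,
                             pixel_pitch = NA_real_), class = "border_mask")
  mask <- border$mask
  width <- border$width_px
  for (p in protocol) {
    k <- p[1]; it <- p[2]
    if (k %% 2 == 0) stop("dilation kernels must be odd, got ", k)
    if (k < 1 || it < 0) stop("invalid protocol entry")
    for (i in seq_len(it))
      mask <- as_mat(EBImage::dilate(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(k, "box"))) > 0.5
    width <- width + 2 * it * (k - 1) / 2
  }
  structure(list(mask = mask, width_px = as.integer(width),
                 pixel_pitch = border$pixel_pitch), class = "border_mask")
}

#' Physical width of a border band
#'
#' @param border A `border_mask`.
#' @param pixel_pitch mm per pixel; defaults to the mask's recorded pitch.
#' @return Width in mm.
#' @export
border_width_mm <- function(border, pixel_pitch = border$pixel_pitch) {
  border$width_px * pixel_pitch
}
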