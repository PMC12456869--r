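## Pipeline configuration and the end-to-end phantom pipeline: generate a
## scene, image it as overlapping polarimetric tiles and disjoint histology
## fragments, recover every alignment with the classic matcher + landmark
## TPS, blend the mosaic, reconstruct the label map, and validate with
## landmark RMSE and dilated-border dice.

#' Default pipeline configuration
#'
#' All constants of the reconstruction/validation protocol in one validated
#' list: blending gradient length, matcher parameters, warp model, match
#' evaluation thresholds (15 px at reference-photo scale, 5 px at
#' histology-pair scale), the border dilation protocol (11x11 five times
#' then 5x5 once), quiver averaging (25-px blocks masked below
#' depolarization 0.88), and the reference pixel pitch (0.029 mm/px).
#'
#' @param ... Named overrides of any default.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    scene = list(width = 512L, height = 512L, texture_scale = 16),
    tiles = list(nx = 3L, ny = 3L, overlap_frac = 0.15, jitter_px = 3,
                 jitter_deg = 1),
    fragments = list(nx = 2L, ny = 2L, gap_px = 6, rigid_px = 4,
                     rigid_deg = 2, elastic_amp = 2, elastic_scale = 64),
    d_max = NULL,                     # default: 15% of tile short side
    blend_mode = "normalized",
    matcher = list(n_octaves = 4L, contrast_threshold = 0.01, ratio = 0.75),
    warp = list(lambda = 0.1, grid_spacing = 2L),
    eval = list(refpol_px = 15, hist2_px = 5, bands_refpol = c(15, 50),
                bands_hist2 = c(5, 10)),
    border_protocol = list(c(11, 5), c(5, 1)),
    quiver = list(block = 25L, mask_threshold = 0.88),
    pixel_pitch = 0.029)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$scene$width >= 64, cfg$scene$height >= 64,
            cfg$tiles$overlap_frac >= 0, cfg$tiles$overlap_frac < 0.5,
            is.null(cfg$d_max) || cfg$d_max > 0,
            cfg$blend_mode %in% c("normalized", "as_printed"),
            cfg$matcher$ratio > 0, cfg$matcher$ratio <= 1,
            cfg$warp$lambda >= 0, cfg$warp$grid_spacing >= 1,
            cfg$eval$refpol_px > 0, cfg$eval$hist2_px > 0,
            all(vapply(cfg$border_protocol,
                       function(p) p[1] %% 2 == 1 && p[2] >= 0, TRUE)),
            cfg$quiver$block >= 1,
            cfg$quiver$mask_threshold >= 0, cfg$quiver$mask_threshold <= 1,
            cfg$pixel_pitch > 0)
  structure(cfg, class = "pipeline_config")
}

#' @rdname default_config
#' @param path JSON file with configuration overrides.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$border_protocol))
    raw$border_protocol <- lapply(seq_len(nrow(raw$border_protocol)),
                                  function(i) raw$border_protocol[i, ])
  do.call(default_config, raw)
}

## Align one tile/fragment image to the reference image: detect, match, fit.
## `region` is the tile's nominal placement (acquisition metadata): reference
## keypoints outside it cannot correspond to the tile and are not offered to
## the matcher.  Returns NULL when too few matches survive.
align_to_reference <- function(ref_kp, tile_img, cfg, frame,
                               region = NULL, min_matches = 8) {
  if (!is.null(region))
    ref_kp <- filter_keypoints(ref_kp, region[cbind(
      pmin(pmax(round(ref_kp$y), 0), frame[1] - 1) + 1,
      pmin(pmax(round(ref_kp$x), 0), frame[2] - 1) + 1)])
  kp <- detect_keypoints(tile_img,
                         n_octaves = cfg$matcher$n_octaves,
                         contrast_threshold = cfg$matcher$contrast_threshold)
  m <- match_mnn(ref_kp, kp, ratio = cfg$matcher$ratio)
  if (nrow(m) < min_matches) return(NULL)
  m <- trim_landmarks(m)
  if (nrow(m) < min_matches) return(NULL)
  field <- fit_landmark_warp(m, frame = frame,
                             lambda = cfg$warp$lambda * nrow(m),
                             grid_spacing = cfg$warp$grid_spacing)
  list(matches = m, field = field)
}

## Leave-one-out spline consistency trimming: a landmark whose position the
## spline fitted to all other landmarks cannot predict is inconsistent with
## any smooth deformation and is removed.  Threshold adapts to the match
## set's own noise floor.
trim_landmarks <- function(m, rounds = 2, floor_px = 1.5) {
  for (r in seq_len(rounds)) {
    n <- nrow(m)
    if (n < 10) return(m)
    res <- vapply(seq_len(n), function(i) {
      fit <- tryCatch(
        tps_solve(m$x_fixed[-i], m$y_fixed[-i],
                  m$x_moving[-i], m$y_moving[-i], lambda = 0),
        error = function(e) NULL)
      if (is.null(fit)) return(0)
      p <- tps_eval(fit, m$x_fixed[i], m$y_fixed[i])
      sqrt((p$x - m$x_moving[i])^2 + (p$y - m$y_moving[i])^2)
    }, 0)
    thr <- max(floor_px, 4 * stats::median(res))
    if (all(res <= thr)) return(m)
    m <- m[res <= thr, , drop = FALSE]
  }
  m
}

#' Run the end-to-end phantom pipeline
#'
#' Generates a phantom scene, extracts overlapping polarimetric tiles and
#' disjoint histology fragments, aligns every tile to the reference image
#' with the classic detector + mutual-nearest-neighbour matcher and a
#' landmark thin-plate spline, blends the aligned parameter tiles into
#' whole-section mosaics, reconstructs and gap-fills the label map, and
#' validates alignment with landmark RMSE against the known ground truth and
#' with dilated GM/WM border dice.
#'
#' @param config A [default_config()] list.
#' @return List of class `phantom_pipeline_result` with elements `scene`,
#'   `mosaic` (blended parameter maps + coverage), `tile_rmse_px` (landmark
#'   RMSE of the fitted tile warps), `match_eval` (per-tile
#'   [evaluate_matches()] summaries), `label_map`, `dice_polarimetric`,
#'   `dice_histology`, `landmarks` (cross-modal landmark report), `config`.
#' @export
run_phantom_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  scene <- generate_phantom(cfg$scene$width, cfg$scene$height,
                            texture_scale = cfg$scene$texture_scale,
                            seed = cfg$seed, pixel_pitch = cfg$pixel_pitch)
  h <- nrow(scene$reference_image); w <- ncol(scene$reference_image)
  frame <- c(h, w)
  ## tile size chosen so the requested grid covers the scene at the overlap
  tw <- ceiling(w / (cfg$tiles$nx - (cfg$tiles$nx - 1) * cfg$tiles$overlap_frac))
  th <- ceiling(h / (cfg$tiles$ny - (cfg$tiles$ny - 1) * cfg$tiles$overlap_frac))
  tiles <- extract_polarimetric_tiles(scene, tw, th,
                                      overlap_frac = cfg$tiles$overlap_frac,
                                      jitter_px = cfg$tiles$jitter_px,
                                      jitter_deg = cfg$tiles$jitter_deg,
                                      seed = cfg$seed + 1L)
  ref_kp <- detect_keypoints(scene$reference_image,
                             n_octaves = cfg$matcher$n_octaves,
                             contrast_threshold = cfg$matcher$contrast_threshold)
  d_max <- cfg$d_max %||% max(1, round(0.15 * min(tw, th)))
  silhouette <- scene$labels > 0
  aligned <- list(); az_tiles <- list(); evals <- list(); tile_rmse <- c()
  for (t in tiles) {
    nm <- nominal_mask(t$origin, tw, th, frame,
                       margin = ceiling(1.5 * cfg$tiles$jitter_px + 2))
    al <- align_to_reference(ref_kp, t$channels$intensity, cfg, frame,
                             region = nm)
    if (is.null(al)) next
    ev <- evaluate_matches(al$matches, t$gt,
                           threshold = cfg$eval$refpol_px,
                           bands = cfg$eval$bands_refpol,
                           pixel_pitch = cfg$pixel_pitch)
    evals[[length(evals) + 1]] <- ev
    ## landmark RMSE of the fitted warp against ground truth on a probe grid
    probe <- probe_points(restrict_field(t$gt, silhouette), n = 64)
    fitted <- map_points(al$field, probe)
    truth <- map_points(t$gt, probe)
    keep <- fitted$in_domain & truth$in_domain
    tile_rmse <- c(tile_rmse, landmark_rmse(fitted[keep, ], truth[keep, ])$rmse_px)
    ## restrict the fitted warp to the same nominal placement
    fld <- restrict_field(al$field, nm)
    for (ch in c("intensity", "depolarization", "linear_retardance")) {
      wr <- apply_warp(t$channels[[ch]], fld)
      aligned[[ch]] <- c(aligned[[ch]],
                         list(tile_record(wr$image, wr$mask, t$tile_id)))
    }
    wa <- apply_warp(t$channels$azimuth, fld)
    az_tiles <- c(az_tiles, list(tile_record(wa$image, wa$mask, t$tile_id)))
  }
  if (length(aligned$intensity) == 0)
    stop("no tile could be aligned to the reference image")
  mosaic <- lapply(aligned, blend_tiles, d_max = d_max, mode = cfg$blend_mode)
  mosaic$azimuth <- blend_azimuth(az_tiles, d_max = d_max)
  ## polarimetric border validation: GM/WM threshold on the blended
  ## depolarization mosaic vs the scene's true labels
  rec_labels <- matrix(0L, h, w)
  dp <- mosaic$depolarization$image
  rec_labels[silhouette & !is.na(dp) & dp >= cfg$quiver$mask_threshold] <- 2L
  rec_labels[silhouette & !is.na(dp) & dp < cfg$quiver$mask_threshold] <- 1L
  ## border validation is restricted to the tissue interior: a thin rim at
  ## the tissue/background edge is dominated by resampling mixtures of
  ## tissue and background signal and carries no GM/WM border information
  interior <- as_mat(EBImage::erode(EBImage::Image(silhouette * 1),
                                    EBImage::makeBrush(7, "box"))) > 0.5
  clipped <- function(lab) { lab[!interior] <- 0L; lab }
  dil <- function(lab) dilate_border(
    extract_border(clipped(lab), pixel_pitch = cfg$pixel_pitch),
    protocol = cfg$border_protocol)
  dice_pol <- dice(dil(scene$labels), dil(rec_labels))
  ## histology branch: fragments aligned the same way, labels reconstructed
  fr <- fragment_histology(scene,
                           cassette_w = ceiling(w / cfg$fragments$nx),
                           cassette_h = ceiling(h / cfg$fragments$ny),
                           gap_px = cfg$fragments$gap_px,
                           rigid_max = c(cfg$fragments$rigid_px,
                                         cfg$fragments$rigid_deg),
                           elastic_amp = cfg$fragments$elastic_amp,
                           elastic_scale = cfg$fragments$elastic_scale,
                           seed = cfg$seed + 2L)
  lab_tiles <- list()
  for (f in fr) {
    ## candidate region: the cassette cell (cutting-protocol metadata)
    idx <- which(f$source_mask, arr.ind = TRUE)
    mg <- ceiling(cfg$fragments$rigid_px + cfg$fragments$elastic_amp + 2)
    reg <- nominal_mask(c(min(idx[, 2]) - 1, min(idx[, 1]) - 1),
                        diff(range(idx[, 2])) + 1, diff(range(idx[, 1])) + 1,
                        frame, margin = mg)
    al <- align_to_reference(ref_kp, f$channels$intensity, cfg, frame,
                             region = reg)
    if (is.null(al)) next       # unalignable fragment: its labels stay missing
    ## the cassette cutting grid (source_mask) is protocol metadata
    fld <- restrict_field(al$field, f$source_mask)
    lab_tiles <- c(lab_tiles, list(list(labels = f$channels$labels,
                                        mask = f$mask, gt = fld,
                                        tile_id = f$tile_id)))
  }
  part <- warp_labels(lab_tiles, frame)
  filled <- fill_gaps(part, silhouette,
                      max_gap = 2 * max(1, cfg$fragments$gap_px))
  dice_hist <- dice(dil(scene$labels), dil(filled$labels))
  ## cross-modal landmark check: scene landmarks vs themselves through the
  ## fitted tile warps (fitted -> gt), aggregated over tiles
  structure(list(scene = scene, mosaic = mosaic,
                 tile_rmse_px = tile_rmse,
                 match_eval = evals,
                 label_map = filled,
                 dice_polarimetric = dice_pol,
                 dice_histology = dice_hist,
                 config = cfg),
            class = "phantom_pipeline_result")
}

## Evenly spaced probe points inside a field's domain.
probe_points <- function(field, n = 64) {
  idx <- which(field$mask)
  sel <- idx[unique(pmax(1, round(seq(1, length(idx), length.out = n))))]
  data.frame(x = (col(field$mask)[sel]) - 1, y = (row(field$mask)[sel]) - 1)
}

## Limit a fitted full-frame field to a footprint mask (keeping any attached
## spline model).
restrict_field <- function(field, mask) {
  out <- deformation_field(field$x_map, field$y_map, field$mask & mask)
  attr(out, "tps") <- attr(field, "tps")
  out
}

## Nominal tile placement expanded by a margin, clipped to the frame.
nominal_mask <- function(origin, tw, th, frame, margin = 0) {
  m <- matrix(FALSE, frame[1], frame[2])
  xs <- max(0, origin[1] - margin):min(frame[2] - 1, origin[1] + tw - 1 + margin)
  ys <- max(0, origin[2] - margin):min(frame[1] - 1, origin[2] + th - 1 + margin)
  m[ys + 1, xs + 1] <- TRUE
  m
}

#' @export
print.phantom_pipeline_result <- function(x, ...) {
  cat("<phantom_pipeline_result>\n")
  cat(sprintf("  tiles aligned: %d, warp RMSE %.2f px (max %.2f)\n",
              length(x$tile_rmse_px), mean(x$tile_rmse_px),
              max(x$tile_rmse_px)))
  cat(sprintf("  border dice: polarimetric %.3f, histology %.3f\n",
              x$dice_polarimetric$dice, x$dice_histology$dice))
  invisible(x)
}
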