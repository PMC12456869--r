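## File formats: float32 TIFF for maps and stacks (the TIFF container holds
## samples in [0, 1], so every channel is stored min-max normalized with the
## affine transform recorded in a JSON sidecar), 8-bit PNG for visualization
## and labels, CSV for keypoint/landmark tables, JSON for configuration and
## reports.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

norm_channel <- function(x) {
  fin <- is.finite(x)
  if (!any(fin)) return(list(data = x * 0, offset = 0, scale = 1, na = !fin))
  lo <- min(x[fin]); hi <- max(x[fin])
  sc <- if (hi > lo) hi - lo else 1
  y <- (x - lo) / sc
  y[!fin] <- 0
  list(data = y, offset = lo, scale = sc, na = !fin)
}

#' Read and write floating-point map TIFFs
#'
#' Multi-channel maps are stored as one 32-bit float TIFF directory per
#' channel, min-max normalized, with channel names and affine
#' (offset, scale) coefficients in a `<path>.json` sidecar.  Non-finite
#' pixels are stored as 0 and restored to `NA` on read.
#'
#' @param maps Named list of numeric matrices (or a single matrix).
#' @param path Output TIFF path.
#' @param meta Extra metadata merged into the sidecar.
#' @return `write_map_tiff`: the path, invisibly.  `read_map_tiff`: a named
#'   list of matrices.
#' @export
write_map_tiff <- function(maps, path, meta = list()) {
  if (is.matrix(maps)) maps <- list(map = maps)
  stopifnot(length(maps) > 0, !is.null(names(maps)))
  normed <- lapply(maps, norm_channel)
  tiff::writeTIFF(lapply(normed, function(n) n$data), path,
                  bits.per.sample = 32L, reduce = FALSE)
  ## NA masks written as extra payload in the sidecar only if small; the
  ## canonical invalid marker is offset + 0 * scale with the na_count noted
  write_sidecar(path, c(list(
    format = "polarmosaic-maps-v1",
    channels = names(maps),
    offset = vapply(normed, function(n) n$offset, 0),
    scale = vapply(normed, function(n) n$scale, 0),
    na_count = vapply(normed, function(n) sum(n$na), 0),
    na_runs = lapply(normed, function(n) encode_runs(n$na)),
    dim = dim(maps[[1]])), meta))
  invisible(path)
}

encode_runs <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = r$lengths, values = as.integer(r$values))
}

decode_runs <- function(runs, dm) {
  if (is.null(runs) || length(runs$lengths) == 0)
    return(matrix(FALSE, dm[1], dm[2]))
  matrix(inverse.rle(list(lengths = as.integer(runs$lengths),
                          values = as.logical(runs$values))), dm[1], dm[2])
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("expected ", length(meta$channels), " channels in ", path,
         ", found ", length(pages))
  dm <- as.integer(meta$dim)
  out <- lapply(seq_along(pages), function(i) {
    x <- pages[[i]] * meta$scale[i] + meta$offset[i]
    x[decode_runs(meta$na_runs[[i]], dm)] <- NA_real_
    x
  })
  stats::setNames(out, meta$channels)
}

#' Read and write 16-channel Mueller-matrix stacks
#'
#' A Mueller image is stored as 16 float TIFF directories in row-major
#' channel order `m00, m01, ..., m33` with the normalization sidecar of
#' [write_map_tiff()].  On read, the validity mask is rebuilt from finite
#' pixels with `m00 > 0`.
#'
#' @param mi A [mueller_image()].
#' @param path TIFF path.
#' @return `load_mueller_stack`: a [mueller_image()].
#' @export
write_mueller_stack <- function(mi, path) {
  stopifnot(inherits(mi, "mueller_image"))
  ch <- paste0("m", rep(0:3, each = 4), rep(0:3, times = 4))
  maps <- stats::setNames(lapply(1:16, function(k) mi$m[, , k]), ch)
  write_map_tiff(maps, path, meta = list(kind = "mueller-stack"))
}

#' @rdname write_mueller_stack
#' @export
load_mueller_stack <- function(path) {
  maps <- read_map_tiff(path)
  if (length(maps) != 16)
    stop("a Mueller stack must have 16 channels (m00..m33), found ",
         length(maps))
  d <- dim(maps[[1]])
  m <- array(0, c(d[1], d[2], 16))
  for (k in 1:16) m[, , k] <- maps[[k]]
  mueller_image(m)
}

#' Read and write deformation fields
#'
#' Stored as a 2-channel float TIFF (`x_map`, `y_map`) plus sidecar with the
#' frame size and the coordinate-convention tag (0-based, x = column, pixel
#' centers at integers).
#'
#' @param field A [deformation_field()].
#' @param path TIFF path.
#' @return `read_field`: a [deformation_field()].
#' @export
write_field <- function(field, path) {
  xm <- field$x_map; ym <- field$y_map
  xm[!field$mask] <- NA_real_; ym[!field$mask] <- NA_real_
  write_map_tiff(list(x_map = xm, y_map = ym), path,
                 meta = list(kind = "deformation-field",
                             convention = "0-based,x=column,pixel-centers"))
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  maps <- read_map_tiff(path)
  stopifnot(all(c("x_map", "y_map") %in% names(maps)))
  deformation_field(maps$x_map, maps$y_map)
}

#' Read and write label maps
#'
#' Labels are written as single-channel 8-bit PNG (value = label index) with
#' a JSON vocabulary sidecar.
#'
#' @param labels Integer matrix or `label_map`.
#' @param path PNG path.
#' @param vocabulary Named vector mapping label names to integer values.
#' @return `read_labels`: a list with `labels` and `vocabulary`.
#' @export
write_labels <- function(labels, path,
                         vocabulary = c(background = 0, GM = 1, WM = 2)) {
  if (inherits(labels, "label_map")) labels <- labels$labels
  png::writePNG(labels / 255, path)
  write_sidecar(path, list(format = "polarmosaic-labels-v1",
                           vocabulary = as.list(vocabulary)))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- read_sidecar(path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  list(labels = matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
       vocabulary = unlist(meta$vocabulary))
}

#' Read and write match tables
#'
#' The CSV dialect is comma-separated, header row, UTF-8, '.' decimal;
#' coordinates are 0-based pixel centers (stated in a leading comment line).
#'
#' @param matches A `match_set` (columns `x_fixed`, `y_fixed`, `x_moving`,
#'   `y_moving`, `score`) or keypoint/landmark table.
#' @param path CSV path.
#' @return `read_matches_csv`: a tibble of class `match_set`.
#' @export
write_matches_csv <- function(matches, path) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines("# polarmosaic matches; coordinates 0-based pixel centers", con)
  utils::write.csv(as.data.frame(matches), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_matches_csv
#' @export
read_matches_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  structure(tibble::as_tibble(df),
            class = c("match_set", class(tibble::tibble())))
}

#' Write a grayscale preview PNG
#'
#' Min-max normalizes a map (NA as black) to an 8-bit PNG.
#'
#' @param map Numeric matrix.
#' @param path PNG path.
#' @export
write_preview_png <- function(map, path) {
  n <- norm_channel(map)
  png::writePNG(n$data, path)
  invisible(path)
}
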