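# Shared fixtures, generated in code (no stored binaries).

# internal coordinate-grid helpers, used heavily when checking fields
grid_x <- polarmosaic:::grid_x
grid_y <- polarmosaic:::grid_y

# Small phantom scene reused across files; generation is deterministic so a
# lazily built cache is safe.
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(128, 128, seed = 42)
    cache
  }
})

# Deterministic pseudo-random mask with one connected invalid blob.
random_mask <- function(h, w, seed = 1) {
  set.seed(seed)
  m <- matrix(TRUE, h, w)
  r0 <- sample(2:(h - 1), 1); c0 <- sample(2:(w - 1), 1)
  m[max(1, r0 - 2):min(h, r0 + 2), max(1, c0 - 2):min(w, c0 + 2)] <- FALSE
  m
}

# Unit-norm descriptor rows embedded in 128-D with prescribed pairwise
# Euclidean distances from the first basis vector.
descriptor_at_distance <- function(d, axis) {
  stopifnot(d >= 0, d <= 2)
  a <- 2 * asin(d / 2)
  v <- numeric(128)
  v[1] <- cos(a); v[axis] <- sin(a)
  v
}

# morphological helpers for excluding mask / class-boundary neighbourhoods
shrink_mask <- function(mask, k) {
  polarmosaic:::as_mat(EBImage::erode(EBImage::Image(mask * 1),
                                      EBImage::makeBrush(k, "box"))) > 0.5
}

near_class_edges <- function(labels, k) {
  edge <- matrix(FALSE, nrow(labels), ncol(labels))
  h <- nrow(labels); w <- ncol(labels)
  edge[-h, ] <- edge[-h, ] | labels[-h, ] != labels[-1, ]
  edge[-1, ] <- edge[-1, ] | labels[-1, ] != labels[-h, ]
  edge[, -w] <- edge[, -w] | labels[, -w] != labels[, -1]
  edge[, -1] <- edge[, -1] | labels[, -1] != labels[, -w]
  polarmosaic:::as_mat(EBImage::dilate(EBImage::Image(edge * 1),
                                       EBImage::makeBrush(k, "box"))) > 0.5
}

as_keypoints <- function(df, desc) {
  structure(tibble::as_tibble(df), descriptors = desc,
            class = c("keypoints", class(tibble::tibble())))
}
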