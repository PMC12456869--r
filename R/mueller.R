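## Mueller-matrix polar decomposition and derived polarimetric products.
##
## Matrices follow the Stokes convention (I, Q, U, V); the polar
## factorization used throughout is M = M_Delta . M_R . M_D (depolarizer,
## retarder, diattenuator), the ordering under which depolarization is
## read off the depolarizer trace and linear retardance / azimuth off the
## retarder submatrix.

#' Mueller rotation matrix
#'
#' Rotation of the polarization reference frame by `theta` degrees.
#' @param theta Rotation angle in degrees.
#' @return 4x4 numeric matrix.
#' @export
mueller_rotation <- function(theta) {
  c2 <- cos(2 * theta * pi / 180); s2 <- sin(2 * theta * pi / 180)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4)
}

#' Linear retarder Mueller matrix
#'
#' Canonical linear retarder with retardance `delta` and fast axis at
#' azimuth `theta`: `R(theta) %*% M_delta %*% R(-theta)`.
#'
#' @param theta Fast-axis azimuth in degrees.
#' @param delta Retardance in degrees.
#' @return 4x4 numeric matrix.
#' @export
linear_retarder_matrix <- function(theta, delta) {
  cd <- cos(delta * pi / 180); sd <- sin(delta * pi / 180)
  M <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                0, 0, cd, sd,
                0, 0, -sd, cd), 4, 4, byrow = TRUE)
  mueller_rotation(theta) %*% M %*% mueller_rotation(-theta)
}

#' Diagonal depolarizer Mueller matrix
#'
#' `diag(1, a, b, c)`; an isotropic depolarizer (`a = b = c`) decomposes to
#' depolarization `1 - a`.
#'
#' @param a,b,c Diagonal depolarization factors, each in `[-1, 1]`.
#' @return 4x4 numeric matrix.
#' @export
depolarizer_matrix <- function(a, b = a, c = a) {
  if (any(abs(c(a, b, c)) > 1))
    stop("depolarizer factors must satisfy |a|, |b|, |c| <= 1")
  diag(c(1, a, b, c))
}

## Clip to [-1, 1], tolerating tiny numerical overshoot.
clip1 <- function(x, tol = 1e-9) {
  if (any(abs(x) > 1 + tol, na.rm = TRUE)) return(rep(NA_real_, length(x)))
  pmin(1, pmax(-1, x))
}

#' Lu-Chipman polar decomposition of a single Mueller matrix
#'
#' Factors `M = M_Delta . M_R . M_D` and reports the scalar parameters used
#' throughout the pipeline: depolarization `Delta = 1 - |tr(m_Delta)| / 3`,
#' total retardance from the retarder trace, linear retardance and azimuth
#' from the retarder submatrix, and diattenuation `|(m01, m02, m03)| / m00`.
#' Outputs are invariant under positive scaling of `M`.
#'
#' @param M 4x4 numeric matrix with `M[1, 1] > 0`.
#' @return Named list: `intensity` (m00), `depolarization` (unitless,
#'   `[0, 1]`), `total_retardance`, `linear_retardance` (degrees, `[0, 180]`),
#'   `azimuth` (degrees, `[0, 180)`), `diattenuation` (`[0, 1]`), and `flag`
#'   (`TRUE` when the retarder extraction was degenerate; parameter outputs
#'   are then `NA`).
#' @export
lu_chipman_decompose <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  m00 <- M[1, 1]
  if (!is.finite(m00) || m00 <= 0)
    return(lc_flagged(m00))
  Mn <- M / m00
  dvec <- Mn[1, 2:4]
  D <- sqrt(sum(dvec^2))
  if (D >= 1) return(lc_flagged(m00))
  if (D > 1e-12) {
    sq <- sqrt(1 - D^2)
    dh <- dvec / D
    mD <- sq * diag(3) + (1 - sq) * (dh %o% dh)
    MD <- rbind(c(1, dvec), cbind(dvec, mD))
    Mp <- Mn %*% solve(MD)
  } else {
    Mp <- Mn
  }
  mp <- Mp[2:4, 2:4]
  S <- mp %*% t(mp)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (sqrt(ev[1]) < 1e-9) {
    ## fully depolarizing: retarder undefined, depolarization well-defined
    return(list(intensity = m00, depolarization = 1, total_retardance = 0,
                linear_retardance = 0, azimuth = 0, diattenuation = D,
                flag = FALSE))
  }
  sgn <- if (det(mp) < 0) -1 else 1
  m_delta <- sgn * (eg$vectors %*% diag(sqrt(ev)) %*% t(eg$vectors))
  if (abs(det(m_delta)) < 1e-12) return(lc_flagged(m00))
  mR <- solve(m_delta, mp)
  Delta <- 1 - abs(sum(diag(m_delta))) / 3
  tr_arg <- clip1((sum(diag(mR)) - 1) / 2)
  lin_arg <- clip1(sqrt((mR[1, 1] + mR[2, 2])^2 + (mR[2, 1] - mR[1, 2])^2) - 1)
  if (is.na(tr_arg) || is.na(lin_arg)) return(lc_flagged(m00))
  R_tot <- acos(tr_arg) * 180 / pi
  delta_lin <- acos(lin_arg) * 180 / pi
  s2t <- mR[3, 1] - mR[1, 3]
  c2t <- mR[2, 3] - mR[3, 2]
  theta <- if (abs(s2t) < 1e-12 && abs(c2t) < 1e-12) 0
           else (0.5 * atan2(s2t, c2t) * 180 / pi) %% 180
  if (theta >= 180 - 1e-9) theta <- 0
  list(intensity = m00,
       depolarization = min(max(Delta, 0), 1),
       total_retardance = R_tot,
       linear_retardance = delta_lin,
       azimuth = theta,
       diattenuation = D,
       flag = FALSE)
}

lc_flagged <- function(m00) {
  list(intensity = m00, depolarization = NA_real_, total_retardance = NA_real_,
       linear_retardance = NA_real_, azimuth = NA_real_,
       diattenuation = NA_real_, flag = TRUE)
}

#' Construct a Mueller image
#'
#' @param m Numeric array `h x w x 16`, channels in row-major order
#'   `m00, m01, ..., m33`.
#' @param valid Logical matrix; default: all channels finite and `m00 > 0`.
#' @return Object of class `mueller_image`.
#' @export
mueller_image <- function(m, valid = NULL) {
  stopifnot(is.array(m), length(dim(m)) == 3, dim(m)[3] == 16)
  if (is.null(valid))
    valid <- apply(is.finite(m), c(1, 2), all) & m[, , 1] > 0
  structure(list(m = m, valid = valid), class = "mueller_image")
}

pixel_matrix <- function(mi, row, col) {
  matrix(mi$m[row, col, ], 4, 4, byrow = TRUE)
}

#' Decompose a Mueller image into polarimetric parameter maps
#'
#' Applies [lu_chipman_decompose()] per pixel.  Pixels flagged by the
#' decomposition (unphysical or degenerate matrices) are removed from the
#' validity mask and set to `NA` in every parameter map.
#'
#' @param mi A [mueller_image()].
#' @return Object of class `polarimetric_maps`: list of matrices
#'   `intensity`, `depolarization`, `linear_retardance`, `azimuth`,
#'   `total_retardance`, `diattenuation`, plus logical `valid`.
#' @export
decompose_image <- function(mi) {
  stopifnot(inherits(mi, "mueller_image"))
  if (!any(mi$valid)) stop("no valid pixels in Mueller image")
  d <- dim(mi$m)
  nm <- c("intensity", "depolarization", "linear_retardance", "azimuth",
          "total_retardance", "diattenuation")
  maps <- stats::setNames(replicate(length(nm),
                                    matrix(NA_real_, d[1], d[2]),
                                    simplify = FALSE), nm)
  valid <- mi$valid
  idx <- which(valid, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    res <- lu_chipman_decompose(pixel_matrix(mi, r, c))
    if (res$flag) {
      valid[r, c] <- FALSE
      next
    }
    maps$intensity[r, c] <- res$intensity
    maps$depolarization[r, c] <- res$depolarization
    maps$linear_retardance[r, c] <- res$linear_retardance
    maps$azimuth[r, c] <- res$azimuth
    maps$total_retardance[r, c] <- res$total_retardance
    maps$diattenuation[r, c] <- res$diattenuation
  }
  if (!any(valid)) stop("all pixels flagged during decomposition")
  structure(c(maps, list(valid = valid)), class = "polarimetric_maps")
}

#' Local variability of an azimuth map
#'
#' Azimuth is a 180-degree-periodic orientation, so variability is measured
#' as the circular variance of doubled angles within a square window:
#' `1 - |mean(cos 2theta, sin 2theta)|`, computed over valid pixels only.
#' 0 means all orientations in the window agree; 1 means complete
#' cancellation (e.g. equal parts 0 and 90 degrees).
#'
#' @param theta Azimuth map in degrees.
#' @param window Odd window width in pixels (>= 3).
#' @param valid Optional logical mask; defaults to finite pixels.
#' @return Matrix in `[0, 1]`, `NA` where the window holds no valid pixel.
#' @export
azimuth_local_variability <- function(theta, window = 25, valid = NULL) {
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3, got ", window)
  if (is.null(valid)) valid <- is.finite(theta)
  th <- theta * pi / 90   # doubled angle in radians
  cs <- cos(th); sn <- sin(th)
  cs[!valid] <- 0; sn[!valid] <- 0
  box <- matrix(1, window, window)
  f <- function(x) as_mat(EBImage::filter2(x, box, boundary = 0))
  n <- f(valid * 1)
  out <- 1 - sqrt(f(cs)^2 + f(sn)^2) / n
  out[n < 0.5] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Block-averaged quiver grid of an azimuth map
#'
#' Averages orientation within non-overlapping `block x block` pixel regions
#' using doubled-angle vector summation, and masks blocks whose mean
#' depolarization falls below `threshold` (by default 0.88, which suppresses
#' gray-matter regions) or which contain no valid pixel.
#'
#' @param theta Azimuth map (degrees).
#' @param depol Depolarization map, same dimension.
#' @param block Block size in pixels (default 25).
#' @param threshold Depolarization mask threshold (default 0.88).
#' @param valid Optional logical mask.
#' @return Object of class `quiver_grid`: list with `orientation` (degrees,
#'   `NA` where masked), `masked` (logical), `depol_mean`, `block`, and
#'   block-center coordinates `cx`, `cy` (0-based pixels).
#' @export
quiver_downsample <- function(theta, depol, block = 25, threshold = 0.88,
                              valid = NULL) {
  stopifnot(block >= 1, all(dim(theta) == dim(depol)))
  if (is.null(valid)) valid <- is.finite(theta) & is.finite(depol)
  h <- nrow(theta); w <- ncol(theta)
  bi <- (row(theta) - 1) %/% block          # block row index
  bj <- (col(theta) - 1) %/% block
  id <- bi + bj * (max(bi) + 1L) + 1L
  nb_r <- max(bi) + 1L; nb_c <- max(bj) + 1L
  th <- theta * pi / 90
  acc <- function(x) {
    v <- rowsum(as.vector(x), as.vector(id))
    m <- matrix(0, nb_r, nb_c)
    m[as.integer(rownames(v))] <- v
    m
  }
  cs <- cos(th); sn <- sin(th)
  cs[!valid] <- 0; sn[!valid] <- 0
  dp <- depol; dp[!valid] <- 0
  n <- acc(valid * 1)
  ori <- (0.5 * atan2(acc(sn), acc(cs)) * 180 / pi) %% 180
  ori[abs(ori - 180) < 1e-9] <- 0
  dmean <- acc(dp) / n
  masked <- n < 0.5 | dmean < threshold
  ori[masked] <- NA_real_
  structure(list(orientation = ori, masked = masked, depol_mean = dmean,
                 block = block,
                 cx = matrix(rep((seq_len(nb_c) - 1) * block + (block - 1) / 2,
                                 each = nb_r), nb_r, nb_c),
                 cy = matrix(rep((seq_len(nb_r) - 1) * block + (block - 1) / 2,
                                 times = nb_c), nb_r, nb_c)),
            class = "quiver_grid")
}
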