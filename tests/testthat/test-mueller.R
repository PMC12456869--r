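# Lu-Chipman decomposition and derived polarimetric products.

test_that("retarder and depolarizer constructors match closed forms", {
  expect_equal(linear_retarder_matrix(0, 0), diag(4))
  expect_equal(linear_retarder_matrix(0, 90),
               matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0,
                        0, 0, 0, 1,
                        0, 0, -1, 0), 4, 4, byrow = TRUE),
               tolerance = 1e-12)
  # rotation composition evaluated symbolically: R(45) M_180 R(-45)
  expect_equal(linear_retarder_matrix(45, 180), diag(c(1, -1, 1, -1)),
               tolerance = 1e-12)
  expect_equal(depolarizer_matrix(1, 1, 1), diag(4))
  expect_error(depolarizer_matrix(1.2), "<=")
})

test_that("decomposition recovers depolarizer-retarder constructions", {
  for (th in c(0, 30, 85, 150)) for (de in c(20, 90, 160)) {
    for (a in c(0.2, 0.9)) {
      M <- depolarizer_matrix(a) %*% linear_retarder_matrix(th, de)
      r <- lu_chipman_decompose(M)
      expect_false(r$flag)
      expect_equal(r$depolarization, 1 - a, tolerance = 1e-6)
      expect_equal(r$linear_retardance, de, tolerance = 1e-6)
      expect_equal(r$azimuth, th, tolerance = 1e-6)
      expect_equal(r$diattenuation, 0, tolerance = 1e-9)
    }
  }
})

test_that("decomposition edge cases behave", {
  r <- lu_chipman_decompose(diag(4))
  expect_equal(unlist(r[c("depolarization", "total_retardance",
                          "linear_retardance", "azimuth", "diattenuation")]),
               c(depolarization = 0, total_retardance = 0,
                 linear_retardance = 0, azimuth = 0, diattenuation = 0),
               tolerance = 1e-9)
  # ideal depolarizer
  r0 <- lu_chipman_decompose(depolarizer_matrix(0, 0, 0))
  expect_equal(r0$depolarization, 1)
  expect_equal(r0$linear_retardance, 0)
  # partial depolarizer closed form: Delta = 1 - (|a|+|b|+|c|)/3
  r6 <- lu_chipman_decompose(depolarizer_matrix(0.6, 0.6, 0.6))
  expect_equal(r6$depolarization, 0.4, tolerance = 1e-9)
  expect_equal(r6$diattenuation, 0, tolerance = 1e-12)
})

test_that("decomposition is scale invariant and azimuth is 180-periodic", {
  M <- depolarizer_matrix(0.85) %*% linear_retarder_matrix(40, 30)
  base <- lu_chipman_decompose(M)
  for (k in c(0.1, 10)) {
    r <- lu_chipman_decompose(k * M)
    expect_equal(r$intensity, k * base$intensity)
    expect_equal(r$depolarization, base$depolarization, tolerance = 1e-9)
    expect_equal(r$linear_retardance, base$linear_retardance,
                 tolerance = 1e-9)
    expect_equal(r$azimuth, base$azimuth, tolerance = 1e-9)
  }
  a <- lu_chipman_decompose(linear_retarder_matrix(25, 60))
  b <- lu_chipman_decompose(linear_retarder_matrix(25 + 180, 60))
  expect_equal(a$azimuth, b$azimuth, tolerance = 1e-9)
})

test_that("decompose_image applies per pixel and propagates masks", {
  M <- linear_retarder_matrix(30, 40)
  m <- array(0, c(6, 5, 16))
  for (k in 1:16) m[, , k] <- M[ceiling(k / 4), (k - 1) %% 4 + 1]
  mi <- mueller_image(m)
  mi$valid[2, 3] <- FALSE
  pm <- decompose_image(mi)
  expect_equal(pm$azimuth[1, 1], 30, tolerance = 1e-9)
  expect_equal(pm$linear_retardance[6, 5], 40, tolerance = 1e-9)
  expect_true(is.na(pm$azimuth[2, 3]))   # masked pixel in -> masked out
  expect_false(pm$valid[2, 3])
  mi_bad <- mueller_image(m, valid = matrix(FALSE, 6, 5))
  expect_error(decompose_image(mi_bad), "no valid pixels")
})

test_that("azimuth local variability matches the doubled-angle formula", {
  expect_error(azimuth_local_variability(matrix(0, 9, 9), window = 4), "odd")
  const <- azimuth_local_variability(matrix(37, 9, 9), window = 3)
  expect_equal(max(abs(const)), 0, tolerance = 1e-12)
  # brute-force oracle on a deterministic pseudo-random map
  set.seed(7)
  th <- matrix(runif(15 * 15, 0, 180), 15, 15)
  v <- azimuth_local_variability(th, window = 5)
  oracle <- function(vals) {
    1 - sqrt(mean(cos(vals * pi / 90))^2 + mean(sin(vals * pi / 90))^2)
  }
  for (p in list(c(5, 5), c(8, 11), c(3, 9))) {
    win <- th[(p[1] - 2):(p[1] + 2), (p[2] - 2):(p[2] + 2)]
    expect_equal(v[p[1], p[2]], oracle(as.vector(win)), tolerance = 1e-9)
  }
  # two orientations in equal proportion: 10 and 20 degrees
  half <- matrix(rep(c(10, 20), each = 10), 4, 5)
  expect_equal(oracle(c(10, 20)),
               1 - sqrt((cos(20 * pi / 180) + cos(40 * pi / 180))^2 +
                        (sin(20 * pi / 180) + sin(40 * pi / 180))^2) / 2,
               tolerance = 1e-12)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("quiver downsampling averages orientations and masks by depolarization", {
  th <- matrix(37, 50, 50); dp <- matrix(0.95, 50, 50)
  q <- quiver_downsample(th, dp, block = 25, threshold = 0.88)
  expect_equal(dim(q$orientation), c(2, 2))
  expect_true(all(abs(q$orientation - 37) < 1e-9))
  expect_false(any(q$masked))
  # below the 0.88 threshold every block is masked
  q2 <- quiver_downsample(th, matrix(0.80, 50, 50))
  expect_true(all(q2$masked))
  # orientations 170 and 10 average to 0 (not 90)
  th3 <- matrix(rep(c(170, 10), each = 1), 2, 2)
  q3 <- quiver_downsample(th3, matrix(0.95, 2, 2), block = 2)
  expect_equal(q3$orientation[1, 1], 0, tolerance = 1e-9)
  expect_equal(nrow(tidy(q)), 4)
})
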