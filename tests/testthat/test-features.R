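# Keypoint detection, matching and match evaluation.

test_that("flat images yield no keypoints and blobs are localized", {
  expect_equal(nrow(detect_keypoints(matrix(0.5, 64, 64))), 0)
  # bright Gaussian blob, sigma = 4: position within 1 px, scale within 25%
  # of the brute-force DoG scale-sweep optimum
  g <- grid_x(128, 128); gy <- grid_y(128, 128)
  img <- 0.1 + 0.9 * exp(-((g - 100)^2 + (gy - 100)^2) / (2 * 16))
  kp <- detect_keypoints(img)
  expect_gt(nrow(kp), 0)
  expect_lt(abs(kp$x[1] - 100), 1)
  expect_lt(abs(kp$y[1] - 100), 1)
  # oracle: |(G_{k s} - G_s) * img| at the blob center, swept over s
  kk <- 2^(1 / 3)
  sweep <- vapply(seq(1, 12, by = 0.1), function(s) {
    d <- polarmosaic:::gaussian_blur(img, kk * s) -
      polarmosaic:::gaussian_blur(img, s)
    abs(d[101, 101])
  }, 0)
  s_star <- seq(1, 12, by = 0.1)[which.max(sweep)]
  expect_lt(abs(kp$scale[1] - s_star) / s_star, 0.25)
})

test_that("keypoint counts are stable under 90-degree rotation", {
  img <- small_scene()$reference_image
  kp <- detect_keypoints(img)
  rot <- t(img)[ncol(img):1, ]          # 90-degree rotation
  kr <- detect_keypoints(rot)
  expect_lt(abs(nrow(kp) - nrow(kr)) / nrow(kp), 0.05)
  # descriptor rows are unit norm
  expect_lt(max(abs(sqrt(rowSums(attr(kp, "descriptors")^2)) - 1)), 1e-6)
})

test_that("the ratio test follows Lowe's rule with a mutual check", {
  A <- descriptor_at_distance(0, 2)
  Ap <- descriptor_at_distance(0.10, 2)
  App <- descriptor_at_distance(0.11, 3)
  fixed <- as_keypoints(data.frame(x = 1, y = 1), rbind(A))
  moving <- as_keypoints(data.frame(x = c(5, 9), y = c(5, 9)),
                         rbind(Ap, App))
  # 0.10 / 0.11 > 0.75: rejected
  expect_equal(nrow(match_mnn(fixed, moving, ratio = 0.75)), 0)
  # 0.10 / 0.11 < 0.95: accepted, and it is the nearest neighbour pair
  m <- match_mnn(fixed, moving, ratio = 0.95)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x_moving, m$y_moving), c(5, 5))
  # identical sets at ratio 1 match one-to-one by identity
  set.seed(2)
  D <- matrix(rnorm(10 * 128), 10)
  D <- D / sqrt(rowSums(D^2))
  kp <- as_keypoints(data.frame(x = 1:10, y = 1:10), D)
  mi <- match_mnn(kp, kp, ratio = 1)
  expect_equal(nrow(mi), 10)
  expect_equal(mi$x_fixed, mi$x_moving)
  # empty side yields an empty match set, not an error
  empty <- detect_keypoints(matrix(0.5, 64, 64))
  expect_equal(nrow(match_mnn(kp, empty)), 0)
})

test_that("match evaluation reproduces hand-computed RMSE and precision", {
  gt <- identity_field(60, 60)
  mk <- function(xm, ym) {
    structure(tibble::tibble(x_fixed = seq_along(xm) * 2,
                             y_fixed = seq_along(xm) * 2,
                             x_moving = seq_along(xm) * 2 + xm,
                             y_moving = seq_along(xm) * 2 + ym,
                             score = 0), class = c("match_set", "tbl_df",
                                                   "tbl", "data.frame"))
  }
  # distances {3, 4}
  ev <- evaluate_matches(mk(c(3, 4), c(0, 0)), gt, threshold = 15)
  expect_equal(ev$rmse_px, sqrt((9 + 16) / 2), tolerance = 1e-9)
  expect_equal(ev$precision_pct, 100)
  # single exact match
  ev0 <- evaluate_matches(mk(0, 0), gt, threshold = 15)
  expect_equal(ev0$rmse_px, 0)
  expect_equal(ev0$precision_pct, 100)
  # distances {10, 20}: precision 50%, RMSE sqrt(250)
  ev2 <- evaluate_matches(mk(c(10, 20), c(0, 0)), gt, threshold = 15)
  expect_equal(ev2$rmse_px, sqrt(250), tolerance = 1e-9)
  expect_equal(ev2$precision_pct, 50)
  expect_equal(unname(ev2$band_counts), c(1, 1, 0))
  # a distance exactly at the threshold is a false positive (strict less-than)
  ev15 <- evaluate_matches(mk(15, 0), gt, threshold = 15)
  expect_equal(ev15$precision_pct, 0)
  # pixel pitch conversion
  evmm <- evaluate_matches(mk(3, 0), gt, threshold = 15, pixel_pitch = 0.029)
  expect_equal(evmm$rmse_mm, 3 * 0.029)
  # out-of-domain fixed points are dropped and counted
  part <- deformation_field(grid_x(60, 60), grid_y(60, 60),
                            mask = grid_x(60, 60) < 5)
  evd <- evaluate_matches(mk(c(0, 0, 0), c(0, 0, 0)), part, threshold = 15)
  expect_equal(evd$n + evd$dropped, 3)
  expect_gt(evd$dropped, 0)
  # tidiers
  expect_equal(nrow(tidy(ev2)), 2)
  expect_equal(glance(ev2)$precision_pct, 50)
})

test_that("the classic pipeline is precise on rigid-only phantom pairs", {
  img <- generate_phantom(192, 192, texture_scale = 16, seed = 21)$reference_image
  pr <- make_pair(img, rigid = c(6, -4, 2), elastic_amp = 0, seed = 22)
  m <- match_mnn(detect_keypoints(img), detect_keypoints(pr$moving))
  expect_gte(nrow(m), 10)
  ev <- evaluate_matches(m, pr$gt, threshold = 15)
  expect_gte(ev$precision_pct, 90)
})

test_that("keypoint filtering keeps descriptors aligned", {
  kp <- detect_keypoints(small_scene()$reference_image)
  sub <- filter_keypoints(kp, kp$x > 60)
  expect_equal(nrow(sub), nrow(attr(sub, "descriptors")))
  expect_true(all(sub$x > 60))
})
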