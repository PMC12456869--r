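# Deformation fields, thin-plate-spline fitting, warping and composition.

rand_pairs <- function(n, seed = 1, w = 60, h = 60) {
  set.seed(seed)
  data.frame(x_fixed = runif(n, 5, w - 5), y_fixed = runif(n, 5, h - 5))
}

test_that("TPS reproduces identity, translation and general affine maps", {
  p <- rand_pairs(12)
  p$x_moving <- p$x_fixed; p$y_moving <- p$y_fixed
  f <- fit_landmark_warp(p, frame = c(40, 40))
  expect_lt(max(abs(f$x_map - grid_x(40, 40))), 1e-9)
  expect_lt(max(abs(f$y_map - grid_y(40, 40))), 1e-9)
  p$x_moving <- p$x_fixed + 10; p$y_moving <- p$y_fixed - 5
  ft <- fit_landmark_warp(p, frame = c(40, 40))
  expect_lt(max(abs(ft$x_map - (grid_x(40, 40) + 10))), 1e-8)
  expect_lt(max(abs(ft$y_map - (grid_y(40, 40) - 5))), 1e-8)
  # general affine, also through the coarse rasterization path
  p$x_moving <- 1.4 * p$x_fixed - 0.3 * p$y_fixed + 7
  p$y_moving <- 0.2 * p$x_fixed + 0.9 * p$y_fixed - 11
  fa <- fit_landmark_warp(p, frame = c(40, 40), grid_spacing = 6)
  expect_lt(max(abs(fa$x_map -
                    (1.4 * grid_x(40, 40) - 0.3 * grid_y(40, 40) + 7))), 1e-8)
})

test_that("TPS interpolates landmarks exactly at lambda 0 and degrades gracefully", {
  p <- rand_pairs(15, seed = 4)
  set.seed(5)
  p$x_moving <- p$x_fixed + rnorm(15, 0, 3)
  p$y_moving <- p$y_fixed + rnorm(15, 0, 3)
  f0 <- fit_landmark_warp(p, frame = c(60, 60), lambda = 0)
  mp <- map_points(f0, data.frame(x = p$x_fixed, y = p$y_fixed))
  expect_lt(max(abs(mp$x - p$x_moving)), 1e-6)
  expect_lt(max(abs(mp$y - p$y_moving)), 1e-6)
  # monotone regularization: landmark residual never decreases with lambda
  resid <- vapply(c(0, 1, 10, 1e3, 1e5), function(l) {
    fl <- fit_landmark_warp(p, frame = c(60, 60), lambda = l)
    m <- map_points(fl, data.frame(x = p$x_fixed, y = p$y_fixed))
    sum((m$x - p$x_moving)^2 + (m$y - p$y_moving)^2)
  }, 0)
  expect_true(all(diff(resid) >= -1e-8))
})

test_that("degenerate landmark configurations raise informative errors", {
  col <- data.frame(x_fixed = c(1, 2, 3, 4), y_fixed = c(1, 2, 3, 4),
                    x_moving = c(1, 2, 3, 4), y_moving = c(2, 3, 4, 5))
  expect_error(fit_landmark_warp(col, frame = c(20, 20)), "singular|collinear")
  dup <- data.frame(x_fixed = c(1, 1, 3), y_fixed = c(2, 2, 4),
                    x_moving = 1:3, y_moving = 1:3)
  expect_error(fit_landmark_warp(dup, frame = c(20, 20)), "duplicate")
  expect_error(fit_landmark_warp(col[1:2, ], frame = c(20, 20)), "at least 3")
})

test_that("TPS recovers a smooth synthetic field at held-out points", {
  # ground truth: gentle sinusoidal displacement, correlation length ~ 30 px
  truth <- function(x, y) list(x = x + 2 * sin(x / 15) + cos(y / 18),
                               y = y - 1.5 * cos(x / 17) + sin(y / 14))
  set.seed(11)
  n <- 30
  xf <- runif(n, 0, 79); yf <- runif(n, 0, 79)
  tv <- truth(xf, yf)
  f <- fit_landmark_warp(data.frame(x_fixed = xf, y_fixed = yf,
                                    x_moving = tv$x, y_moving = tv$y),
                         frame = c(80, 80))
  ho <- data.frame(x = runif(50, 10, 70), y = runif(50, 10, 70))
  pred <- map_points(f, ho)
  tr <- truth(ho$x, ho$y)
  expect_lt(max(sqrt((pred$x - tr$x)^2 + (pred$y - tr$y)^2)), 1)
})

test_that("apply_warp resamples correctly and flags invalid output", {
  img <- matrix(runif(400), 20, 20)
  idw <- apply_warp(img, identity_field(20, 20))
  expect_equal(idw$image, img)
  expect_true(all(idw$mask))
  sh <- apply_warp(img, translation_field(20, 20, 3, -2),
                   interpolation = "nearest")
  expect_equal(sh$image[5, 5], img[3, 8])   # out(x,y) = img(x+3, y-2)
  expect_false(all(sh$mask))                # shifted-out pixels invalid
  expect_true(is.na(sh$image[1, 18]))
})

test_that("warp then inverse-warp round-trips a smooth image", {
  sc <- small_scene()
  img <- sc$reference_image
  pr <- make_pair(img, rigid = c(4, -2, 1.5), elastic_amp = 2,
                  elastic_scale = 48, seed = 9)
  # gt maps fixed -> moving; warping moving back through gt recovers fixed
  rec <- apply_warp(pr$moving, pr$gt)
  inner <- matrix(FALSE, 128, 128); inner[20:108, 20:108] <- TRUE
  ok <- rec$mask & inner & pr$moving_mask & !near_class_edges(sc$labels, 7)
  expect_lt(max(abs(rec$image[ok] - img[ok])), 0.02 * diff(range(img)))
})

test_that("map_points and apply_warp agree on impulse images", {
  fld <- translation_field(30, 30, 6, 4)
  imp <- matrix(0, 30, 30); imp[15, 20] <- 1   # impulse at (x, y) = (19, 14)
  wr <- apply_warp(imp, fld, interpolation = "nearest")
  hit <- which(wr$image == 1, arr.ind = TRUE)
  mp <- map_points(fld, data.frame(x = hit[1, 2] - 1, y = hit[1, 1] - 1))
  expect_equal(c(mp$x, mp$y), c(19, 14))
})

test_that("composition chains fields and respects associativity", {
  f <- translation_field(40, 40, 3, 1)
  g <- translation_field(40, 40, -1, 2)
  h <- translation_field(40, 40, 2, -1)
  cfg <- compose_fields(f, g)
  expect_equal(cfg$x_map[10, 10], grid_x(40, 40)[10, 10] + 2)
  idc <- compose_fields(identity_field(40, 40), f)
  expect_equal(idc$x_map[f$mask & idc$mask], f$x_map[f$mask & idc$mask])
  lhs <- compose_fields(compose_fields(f, g), h)
  rhs <- compose_fields(f, compose_fields(g, h))
  m <- lhs$mask & rhs$mask
  expect_true(any(m))
  expect_lt(max(abs(lhs$x_map[m] - rhs$x_map[m])), 1e-9)
  expect_lt(max(abs(lhs$y_map[m] - rhs$y_map[m])), 1e-9)
  # map_points consistency with sequential mapping
  pts <- data.frame(x = c(5, 20), y = c(7, 30))
  seq2 <- map_points(g, map_points(f, pts))
  comp <- map_points(cfg, pts)
  expect_lt(max(abs(seq2$x - comp$x), abs(seq2$y - comp$y)), 0.1)
})

test_that("numerical inversion round-trips within half a pixel", {
  sc <- small_scene()
  pr <- make_pair(sc$reference_image, rigid = c(5, -3, 2), elastic_amp = 2,
                  elastic_scale = 48, seed = 13)
  inv <- invert_field(pr$gt)
  comp <- compose_fields(pr$gt, inv)
  d <- dim(comp$x_map)
  disp <- sqrt((comp$x_map - grid_x(d[1], d[2]))^2 +
               (comp$y_map - grid_y(d[1], d[2]))^2)
  expect_lt(max(disp[comp$mask]), 0.5)
  expect_true(polarmosaic:::field_jacobian_ok(pr$gt))
})
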