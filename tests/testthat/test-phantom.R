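# Synthetic phantom: scenes, overlapping tiles, disjoint fragments, pairs.

test_that("phantom generation is deterministic and class-separable", {
  expect_error(generate_phantom(32, 200), "64")
  a <- generate_phantom(96, 96, seed = 3)
  b <- generate_phantom(96, 96, seed = 3)
  expect_identical(a$reference_image, b$reference_image)
  expect_identical(a$mueller$m, b$mueller$m)
  expect_true(all(c(0, 1, 2) %in% a$labels))
  # depolarization separates classes exactly at the 0.88 masking threshold
  expect_equal(mean(a$params$depolarization[a$labels == 2] >= 0.88), 1)
  expect_equal(mean(a$params$depolarization[a$labels == 1] < 0.88), 1)
  expect_true(all(a$reference_image >= 0 & a$reference_image <= 1))
})

test_that("decomposing the phantom Mueller field recovers the parameter maps", {
  sc <- small_scene()
  rows <- 40:75; cols <- 50:85    # tissue-containing subregion
  mi <- mueller_image(sc$mueller$m[rows, cols, , drop = FALSE])
  pm <- decompose_image(mi)
  expect_lt(max(abs(pm$depolarization -
                    sc$params$depolarization[rows, cols])), 1e-6)
  expect_lt(max(abs(pm$linear_retardance -
                    sc$params$linear_retardance[rows, cols])), 1e-6)
  in_tissue <- sc$labels[rows, cols] > 0
  az_err <- abs(pm$azimuth - sc$params$azimuth[rows, cols])
  expect_lt(max(pmin(az_err, 180 - az_err)[in_tissue]), 1e-6)
  expect_equal(pm$intensity, sc$params$intensity[rows, cols])
})

test_that("tile grids overlap as requested and ground truth is exact", {
  sc <- small_scene()
  tiles <- extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.15,
                                      jitter_px = 0, jitter_deg = 0, seed = 5,
                                      gain_jitter = 0, offset_jitter = 0)
  origins <- t(vapply(tiles, function(t) t$origin, c(0, 0)))
  xs <- sort(unique(origins[, 1]))
  expect_equal(xs[2] - xs[1], 48 - round(0.15 * 48))  # ~15% shared width
  # jitter-free ground truth is exactly the nominal translation
  t1 <- tiles[[2]]
  expect_equal(t1$gt$x_map[t1$gt$mask][1] -
               grid_x(128, 128)[t1$gt$mask][1], -t1$origin[1])
  d <- dim(t1$gt$x_map)
  disp_x <- t1$gt$x_map + t1$origin[1] - grid_x(d[1], d[2])
  expect_lt(max(abs(disp_x[t1$gt$mask])), 1e-12)
  # tiles cover the full scene
  cover <- Reduce(`|`, lapply(tiles, function(t) t$gt$mask))
  expect_true(all(cover))
  expect_error(extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.7),
               "overlap")
})

test_that("jittered tiles stay within the stated displacement bound", {
  sc <- small_scene()
  tiles <- extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.15,
                                      jitter_px = 3, jitter_deg = 0, seed = 6)
  for (t in tiles) {
    # corner displacement from nominal = |translation jitter| <= 3 * sqrt(2)
    expect_lte(sqrt(sum(t$rigid[c("dx", "dy")]^2)), 3 * sqrt(2) + 1e-12)
  }
  # determinism
  again <- extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.15,
                                      jitter_px = 3, jitter_deg = 0, seed = 6)
  expect_identical(tiles[[1]]$channels$intensity,
                   again[[1]]$channels$intensity)
})

test_that("tiles are self-consistent with their ground-truth maps", {
  sc <- small_scene()
  # integer nominal translations: warping the tile back through its ground
  # truth reproduces the scene exactly
  t0 <- extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.15,
                                   jitter_px = 0, jitter_deg = 0, seed = 7,
                                   gain_jitter = 0, offset_jitter = 0)[[2]]
  rec0 <- apply_warp(t0$channels$intensity, t0$gt)
  expect_lt(max(abs(rec0$image[rec0$mask] -
                    sc$reference_image[rec0$mask])), 1e-12)
  # fractional rigid perturbations: within bilinear interpolation error of
  # the band-limited texture, away from mask edges and the (discontinuous)
  # class boundaries
  tiles <- extract_polarimetric_tiles(sc, 48, 48, overlap_frac = 0.15,
                                      jitter_px = 2, jitter_deg = 1, seed = 7,
                                      gain_jitter = 0, offset_jitter = 0)
  t <- tiles[[1]]
  rec <- apply_warp(t$channels$intensity, t$gt)
  core <- shrink_mask(t$gt$mask, 5)
  ok <- rec$mask & core & !near_class_edges(sc$labels, 7)
  expect_lt(max(abs(rec$image[ok] - sc$reference_image[ok])), 0.02)
})

test_that("histology fragments are disjoint with the prescribed gap", {
  sc <- small_scene()
  fr <- fragment_histology(sc, 64, 64, gap_px = 6, rigid_max = c(3, 1),
                           elastic_amp = 2, elastic_scale = 48, seed = 8)
  expect_length(fr, 4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sum(fr[[i]]$source_mask & fr[[j]]$source_mask), 0)
  # a ~6 px unlabeled band between horizontally adjacent fragments
  gap_cols <- which(!(fr[[1]]$source_mask | fr[[2]]$source_mask)[32, 1:128])
  expect_equal(length(gap_cols), 6)
  expect_error(fragment_histology(sc, 64, 64, elastic_amp = 30,
                                  elastic_scale = 48), "folding")
})

test_that("undeformed fragments reassemble the scene exactly", {
  sc <- small_scene()
  fr <- fragment_histology(sc, 64, 64, gap_px = 0, rigid_max = c(0, 0),
                           elastic_amp = 0, seed = 9, gain_jitter = 0)
  lm <- warp_labels(lapply(fr, function(f)
    list(labels = f$channels$labels, mask = f$mask, gt = f$gt,
         tile_id = f$tile_id)), frame = c(128, 128))
  expect_equal(lm$labels, sc$labels)
  # label vocabulary is preserved (no interpolation-invented labels)
  expect_true(all(unique(as.vector(lm$labels)) %in%
                  unique(as.vector(sc$labels))))
})

test_that("elastic displacement is bounded by its amplitude", {
  img <- small_scene()$reference_image
  pr <- make_pair(img, rigid = c(0, 0, 0), elastic_amp = 4,
                  elastic_scale = 64, seed = 10)
  disp <- pmax(abs(pr$gt$x_map - grid_x(128, 128)),
               abs(pr$gt$y_map - grid_y(128, 128)))
  expect_lte(max(disp), 4 * (1 + 1e-9))
  expect_gt(max(disp), 3.99)   # amplitude normalization is tight
  expect_true(polarmosaic:::field_jacobian_ok(pr$gt))
})

test_that("make_pair constructions have exact ground truth", {
  img <- small_scene()$reference_image
  id <- make_pair(img, rigid = c(0, 0, 0), elastic_amp = 0, seed = 1)
  expect_equal(id$moving, img)
  expect_equal(id$gt$x_map, grid_x(128, 128))
  tr <- make_pair(img, rigid = c(10, 0, 0), elastic_amp = 0, seed = 1)
  expect_equal(tr$gt$x_map, grid_x(128, 128) + 10)
  expect_equal(tr$gt$y_map, grid_y(128, 128))
  expect_equal(tr$moving[20, 31], img[20, 21])   # content shifted by +10 in x
  rt <- make_pair(img, rigid = c(5, -3, 2), elastic_amp = 2,
                  elastic_scale = 48, seed = 2)
  inv <- invert_field(rt$gt)
  comp <- compose_fields(rt$gt, inv)
  disp <- sqrt((comp$x_map - grid_x(128, 128))^2 +
               (comp$y_map - grid_y(128, 128))^2)
  expect_lt(max(disp[comp$mask]), 0.5)
})
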