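test_that("template matching maximizes zero-mean NCC with exact oracle agreement", {
  ph <- fixture_phantom()
  aip <- fixture_aip(ph)
  tpl <- aip[21:36, 31:46]

  m <- match_template(aip, tpl)
  expect_equal(m$pos_px, c(21L, 31L))
  expect_equal(m$score, 1.0, tolerance = 1e-9)

  # NCC is invariant to positive affine intensity changes of the template
  m2 <- match_template(aip, 2.5 * tpl + 7)
  expect_equal(m2$pos_px, c(21L, 31L))
  expect_equal(m2$score, 1.0, tolerance = 1e-9)

  # exact agreement with the brute-force correlation loop on noisy data
  set.seed(12)
  img <- aip[1:40, 1:40] + matrix(rnorm(1600, sd = 0.05), 40)
  o <- ncc_brute_force(img, tpl)
  f <- match_template(img, tpl)
  expect_equal(f$pos_px, as.integer(o$pos))
  expect_equal(f$score, o$score, tolerance = 1e-9)

  # planted crop relocated within 1 px under 5% noise
  rng <- diff(range(aip))
  for (i in 1:10) {
    set.seed(300 + i)
    noisy <- aip + matrix(rnorm(length(aip), sd = 0.05 * rng), nrow(aip))
    mi <- match_template(noisy, tpl, expected_px = c(21, 31), window_px = 12)
    expect_lte(max(abs(mi$pos_px - c(21, 31))), 1)
  }

  expect_error(match_template(aip, matrix(1, 5, 5)), "degenerate")
})

test_that("ROI overlays rasterize blocks with unique labels on the brain grid", {
  geom <- grid_geometry(c(0, 0, 0), 25, c(60, 60, 24))
  none <- build_overlay(data.frame(), geom)
  expect_true(all(none$labels == 0L))

  rois <- data.frame(label = 1:3, x_um = c(400, 900, 400),
                     y_um = c(400, 900, 1100), fov_mm = 0.5,
                     slice_index = c(0L, 0L, 1L), z0_um = 0,
                     thickness_um = 250, mode = "auto")
  ov <- build_overlay(rois, geom, slice_thickness_um = 200)

  # a 0.5 mm ROI on a 25 um grid is a 20 x 20 voxel block laterally
  blk <- which(ov$labels == 1L, arr.ind = TRUE)
  expect_equal(length(unique(blk[, 1])), 20L)
  expect_equal(length(unique(blk[, 2])), 20L)
  expect_equal(sort(unique(as.integer(ov$labels[ov$labels > 0]))), 1:3)

  # overlapping ROIs collide with a warning, last writer wins
  clash <- rois[c(1, 1), ]
  clash$label <- c(1L, 2L)
  expect_warning(ovc <- build_overlay(clash, geom), "collide")
  expect_equal(sort(unique(as.integer(ovc$labels[ovc$labels > 0]))), 2L)
})

test_that("affine application is a label-conserving nearest-neighbour pull-back", {
  geom <- grid_geometry(c(0, 0, 0), 25, c(40, 40, 20))
  rois <- data.frame(label = 1L, x_um = 400, y_um = 400, fov_mm = 0.3,
                     slice_index = 0L, z0_um = 100, thickness_um = 150,
                     mode = "auto")
  ov <- build_overlay(rois, geom)

  ident <- apply_affine(ov, diag(4), geom)
  expect_identical(ident$labels, ov$labels)

  # pure one-voxel translation shifts the block exactly
  tr <- diag(4); tr[1, 4] <- 25
  sh <- apply_affine(ov, tr, geom)
  expect_identical(sh$labels[2:40, , ], ov$labels[1:39, , ])

  # round trip T then T^-1 keeps the block (Dice >= 0.95)
  rot <- diag(4)
  th <- 10 * pi / 180
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot[1:2, 4] <- c(120, -60)
  rt <- apply_affine(apply_affine(ov, rot, geom), solve(rot), geom)
  a <- ov$labels == 1L; b <- rt$labels == 1L
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.95)

  # no labels are invented
  expect_true(all(unique(as.integer(rt$labels)) %in%
                    unique(as.integer(ov$labels))))
  expect_error(apply_affine(ov, matrix(0, 4, 4), geom), "singular")
})

test_that("structure fractions and fiber flags follow the atlas histogram", {
  geom <- grid_geometry(c(0, 0, 0), 25, c(40, 40, 20))
  atlas <- array(5L, c(40, 40, 20))
  atlas[21:40, , ] <- 6L

  inside <- data.frame(label = 1L, x_um = 250, y_um = 250, fov_mm = 0.25,
                       slice_index = 0L, z0_um = 0, thickness_um = 200,
                       mode = "auto")
  ov1 <- build_overlay(inside, geom)
  sf1 <- structure_fractions(ov1, atlas, fiber_labels = 6L)
  expect_equal(sf1$fractions$structure, 5L)
  expect_equal(sf1$fractions$fraction, 1.0)
  expect_false(sf1$fiber_flag[["1"]])

  # a block straddling the two labels evenly
  strad <- data.frame(label = 1L, x_um = 500, y_um = 500, fov_mm = 0.5,
                      slice_index = 0L, z0_um = 0, thickness_um = 200,
                      mode = "auto")
  ov2 <- build_overlay(strad, geom)
  sf2 <- structure_fractions(ov2, atlas, fiber_labels = 6L)
  fr <- sf2$fractions$fraction
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  expect_true(all(abs(fr - 0.5) <= 0.05 + 1 / 20))
  expect_true(sf2$fiber_flag[["1"]])
})

test_that("per-ROI metric means equal the brute-force voxel loop", {
  geom <- grid_geometry(c(0, 0, 0), 25, c(40, 40, 20))
  rois <- data.frame(label = 1:2, x_um = c(300, 700), y_um = c(300, 700),
                     fov_mm = 0.3, slice_index = 0L, z0_um = c(0, 100),
                     thickness_um = 200, mode = "auto")
  ov <- build_overlay(rois, geom)

  const <- array(0.37, c(40, 40, 20))
  expect_equal(unname(roi_metric_average(ov, const)), c(0.37, 0.37))

  metric <- array(0.2, c(40, 40, 20))
  metric[, , 11:20] <- 0.6
  m <- roi_metric_average(ov, metric)
  # ROI 1 spans z 0..200 um = layers 1..8 entirely in the 0.2 region
  expect_equal(unname(m["1"]), 0.2)

  set.seed(13)
  rnd <- array(runif(40 * 40 * 20), c(40, 40, 20))
  rnd[sample(length(rnd), 500)] <- NaN
  fast <- roi_metric_average(ov, rnd)
  for (l in 1:2) {
    v <- rnd[ov$labels == l]
    expect_equal(unname(fast[as.character(l)]), mean(v[is.finite(v)]))
  }
})
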