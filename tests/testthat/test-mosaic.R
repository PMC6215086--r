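test_that("phase correlation recovers planted circular shifts exactly", {
  set.seed(5)
  a <- matrix(rnorm(64 * 64), 64)
  expect_equal(phase_correlation(a, a)$shift, c(0, 0))

  shift_by <- function(m, s) m[(seq_len(nrow(m)) - 1 - s[1]) %% nrow(m) + 1,
                               (seq_len(ncol(m)) - 1 - s[2]) %% ncol(m) + 1]
  b <- shift_by(a, c(7, -3))
  expect_equal(phase_correlation(a, b)$shift, c(7, -3))

  for (i in 1:50) {
    set.seed(1000 + i)
    img <- matrix(rnorm(48 * 48), 48)
    s <- sample(-16:16, 2, replace = TRUE)
    expect_equal(phase_correlation(img, shift_by(img, s))$shift, as.numeric(s))
  }

  expect_error(phase_correlation(matrix(1, 8, 8), a[1:8, 1:8]), "degenerate")
})

test_that("stage calibration solves p = A pM + b and round-trips", {
  pm <- as.matrix(expand.grid(c(0, 1000, 2000), c(0, 1000, 2000)))

  # orthogonal unit stage with a pure scale
  m1 <- calibrate_stage(pm, pm %*% (0.25 * diag(2)))
  expect_equal(m1$A, 0.25 * diag(2), tolerance = 1e-9)
  expect_equal(m1$b, c(0, 0), tolerance = 1e-9)

  # 1 degree inter-axis shear, noiseless: exact elementwise recovery
  th <- pi / 180
  A <- matrix(c(0.25, 0, 0.25 * sin(th), 0.25 * cos(th)), 2)
  b <- c(12.5, -40)
  m2 <- calibrate_stage(pm, t(A %*% t(pm) + b))
  expect_equal(m2$A, A, tolerance = 1e-9)
  expect_equal(m2$b, b, tolerance = 1e-9)
  expect_lt(m2$residual_rms_um, 1e-9)

  # 0.5 um measurement noise: A within 1e-3 relative over 100 trials
  pm_big <- as.matrix(expand.grid(seq(0, 40000, 10000), seq(0, 40000, 10000)))
  set.seed(9)
  for (trial in 1:100) {
    noisy <- t(A %*% t(pm_big) + b) + matrix(rnorm(2 * nrow(pm_big), sd = 0.5),
                                             ncol = 2)
    mt <- calibrate_stage(pm_big, noisy)
    expect_lt(max(abs(mt$A - A)) / max(abs(A)), 1e-3)
  }

  # collinear displacements are rejected
  expect_error(calibrate_stage(cbind(1:5, 2 * (1:5)), cbind(1:5, 2 * (1:5))),
               "collinear|rank")

  # microstep conversion round-trips through the inverse map
  p <- microsteps_to_cartesian(m2, c(1234, -567))
  expect_equal(cartesian_to_microsteps(m2, p), c(1234, -567), tolerance = 1e-9)
  expect_equal(microsteps_to_cartesian(stage_model_identity(), c(3, 4)), c(3, 4))
})

test_that("blending weights form a partition of unity and stitch seamlessly", {
  grid <- list(origin_um = c(0, 0), spacing_um = 25, dim = c(36, 20))
  one <- blend_weights(rbind(c(0, 900, 0, 500)), grid)
  expect_equal(range(one[[1]]), c(1, 1))

  # two tiles at 20% overlap: monotone handover, sums to 1 +- 1e-6
  fp <- rbind(c(0, 500, 0, 500), c(400, 900, 0, 500))
  w <- blend_weights(fp, grid)
  tot <- w[[1]] + w[[2]]
  expect_lt(max(abs(tot - 1)), 1e-6)
  ov <- w[[1]][17:20, 10]                     # across the overlap zone
  expect_true(all(diff(ov) < 0))              # tile 1 fades out monotonically

  # heat-kernel variant is also a partition of unity
  wh <- blend_weights(fp, grid, method = "heat")
  expect_lt(max(abs(wh[[1]] + wh[[2]] - 1)), 1e-6)

  # stitching constant tiles yields a constant mosaic
  tiles <- lapply(c(0, 400), function(x0)
    intensity_volume(array(2.5, c(3, 20, 20)), c(6, 25, 25), origin_um = c(x0, 0)))
  sm <- stitch_slice(tiles)
  expect_lt(max(abs(sm$volume - 2.5)), 1e-6)
})

test_that("slice stitching reassembles tiles cut from one slice exactly", {
  ts <- tile_spec()
  # 3 x 3 grid of 0.5 mm tiles at 20% overlap spans 1.3 mm
  grid <- tile_raster(0, 0, 3, 3, ts)
  set.seed(1)
  big <- abs(matrix(rnorm(52 * 52), 52))      # 1.3 mm at 25 um/px
  tiles <- lapply(seq_len(nrow(grid)), function(t) {
    ix <- grid$x0_um[t] / 25; iy <- grid$y0_um[t] / 25
    intensity_volume(array(big[ix + 1:20, iy + 1:20], c(1, 20, 20)),
                     c(6, 25, 25), origin_um = c(grid$x0_um[t], grid$y0_um[t]))
  })
  sm <- stitch_slice(tiles)
  expect_equal(sm$grid$dim * sm$grid$spacing_um, c(1300, 1300))
  expect_lt(max(abs(sm$volume[1, , ] - big)), 1e-6)

  # AIP of an all-ones slice is 1 everywhere covered
  ones <- lapply(tiles, function(t) {
    t$intensity[] <- 1; t
  })
  expect_equal(range(stitch_slice(ones)$aip), c(1, 1), tolerance = 1e-9)

  # translation equivariance: shifting all tiles shifts the mosaic
  shifted <- lapply(tiles, function(t) {
    t$origin_um <- t$origin_um + c(50, 75); t
  })
  sm2 <- stitch_slice(shifted)
  expect_equal(sm2$grid$origin_um, sm$grid$origin_um + c(50, 75))
  expect_equal(sm2$volume, sm$volume, tolerance = 1e-12)

  expect_warning(stitch_slice(list(tiles[[1]], {
    t <- tiles[[2]]; t$origin_um <- c(5000, 5000); t
  })), "uncovered")
})

test_that("brain assembly blends 200 um slices with 100 um overlap onto 25 um", {
  set.seed(2)
  nz <- 28; nx <- 30; ny <- 30
  truth <- array(0, c(nz, nx, ny))
  for (z in seq_len(nz)) truth[z, , ] <- abs(matrix(rnorm(nx * ny, mean = z / 8), nx))
  zpos <- c(0, 200, 400)
  slices <- lapply(seq_along(zpos), function(s) {
    i0 <- zpos[s] / 25
    nzs <- min(12L, nz - i0)                  # 300 um imaging depth
    vol <- truth[i0 + seq_len(nzs), , , drop = FALSE]
    structure(list(volume = vol, aip = apply(vol, c(2, 3), mean),
                   weights = NULL,
                   grid = list(origin_um = c(0, 0), spacing_um = 25,
                               dim = c(nx, ny)),
                   voxel_size_um = c(25, 25, 25), slice_index = s - 1L,
                   z_position_um = zpos[s], thickness_um = nzs * 25),
              class = "slice_mosaic")
  })
  bv <- assemble_brain(slices)
  expect_equal(bv$voxel_size_um, c(25, 25, 25))
  expect_gte(cor(as.vector(bv$intensity), as.vector(truth)), 0.99)

  # slice blending weights sum to 1 in every overlap
  expect_lt(max(abs(rowSums(bv$slice_weights) - 1)), 1e-6)

  # a single slice assembles to a resampled copy of itself
  one <- assemble_brain(slices[1])
  expect_equal(one$intensity, slices[[1]]$volume, tolerance = 1e-12)

  # a z gap is assembled with a warning
  gap <- slices
  gap[[3]]$z_position_um <- 900
  expect_warning(assemble_brain(gap), "gap")
})

test_that("polygons are covered by the minimal 0.5 mm / 20% overlap tile grid", {
  ts <- tile_spec()
  # polygon inside one tile
  small <- rbind(c(0, 0), c(300, 0), c(300, 200), c(0, 200))
  expect_equal(nrow(polygon_to_tiles(small, ts)), 1L)

  # 1.3 x 0.5 mm rectangle -> 3 x 1 tiles
  rect <- rbind(c(0, 0), c(1300, 0), c(1300, 500), c(0, 500))
  tl <- polygon_to_tiles(rect, ts)
  expect_equal(nrow(tl), 3L)
  expect_equal(sort(tl$x0_um), c(0, 400, 800))

  # every vertex of random polygons is covered by at least one tile
  set.seed(3)
  for (i in 1:10) {
    th <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 200, 1500)
    poly <- cbind(r * cos(th), r * sin(th))
    tl <- polygon_to_tiles(poly, ts)
    fov <- ts$fov_mm * 1000
    covered <- vapply(seq_len(nrow(poly)), function(v)
      any(poly[v, 1] >= tl$x0_um & poly[v, 1] <= tl$x0_um + fov &
            poly[v, 2] >= tl$y0_um & poly[v, 2] <= tl$y0_um + fov), TRUE)
    expect_true(all(covered))
  }

  bow <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(polygon_to_tiles(bow, ts), "self-intersecting")
})
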