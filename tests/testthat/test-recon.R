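test_that("A-line reconstruction behaves as the apodized half-range inverse transform", {
  ls <- fixture_laser()
  n <- ls$n_k_samples
  kk <- k_grid(ls)

  # fringe equal to the reference reconstructs to all zeros
  f <- sin(seq_len(n))
  expect_equal(reconstruct_aline(f, f, ls), rep(0, n / 2))

  # the apodization window is peak-normalized in wavelength
  expect_equal(apodization_weight(1310, ls), 1.0)
  expect_equal(apodization_weight(1310 + 20, ls), exp(-1 / 2))

  # a single cosine at depth z0 peaks at the nearest depth bin
  z0 <- 100
  fr <- cos(2 * kk * ls$n_medium * z0 * 1e3)
  prof <- reconstruct_aline(fr, rep(0, n), ls)
  zax <- depth_axis_um(ls)
  expect_equal(which.max(prof), which.min(abs(zax - z0)))

  # doubling the fringe amplitude quadruples intensity everywhere
  expect_equal(reconstruct_aline(2 * fr, rep(0, n), ls), 4 * prof,
               tolerance = 1e-12)

  expect_error(reconstruct_aline(fr[-1], rep(0, n), ls), "length")
})

test_that("tile reconstruction uses the tile-mean reference and half axial range", {
  ph <- fixture_phantom()
  ft <- simulate_tile_fringes(ph, tile_placement(200, 200, 0, 100), seed = 3)

  vol <- reconstruct_tile(ft)
  expect_equal(dim(vol$intensity)[1], fixture_laser()$n_k_samples / 2)
  expect_true(all(vol$intensity >= 0) && all(is.finite(vol$intensity)))
  expect_gte(cor(as.vector(vol$intensity), as.vector(ft$truth)), 0.99)

  # a tile of identical fringes reconstructs to zero (each equals the mean)
  same <- ft
  same$fringes <- array(rep(ft$fringes[, 1, 1], prod(dim(ft$fringes)[2:3])),
                        dim(ft$fringes))
  expect_equal(max(reconstruct_tile(same)$intensity), 0)

  bad <- ft
  bad$fringes[1] <- NaN
  expect_error(reconstruct_tile(bad), "finite")
})

test_that("attenuation coefficients are recovered from model profiles", {
  ls <- fixture_laser()
  dz <- depth_bin_um(ls)
  as_vol <- function(prof, nlat = 1) {
    intensity_volume(array(rep(prof, nlat * nlat), c(length(prof), nlat, nlat)),
                     c(dz, 25, 25), focal_depth_um = 150)
  }

  # noiseless recovery within 1% relative
  for (mu in c(1, 2, 4, 8)) {
    fit <- fit_attenuation(as_vol(model_profile(mu)), 0, z_r_um = 1000)
    expect_lt(abs(fit$mu_median - mu) / mu, 0.01)
  }

  # pure confocal decay (mu = 0) recovered as <= 0.01 mm^-1
  fit0 <- fit_attenuation(as_vol(model_profile(0)), 0, z_r_um = 1000)
  expect_lte(fit0$mu_median, 0.01)

  # bias < 5% across the sweep at 1% intensity noise
  set.seed(11)
  for (mu in c(1, 2, 4, 8)) {
    prof <- model_profile(mu)
    arr <- array(rep(prof, 64), c(length(prof), 8, 8))
    arr <- pmax(arr + array(rnorm(length(arr), sd = 0.01 * max(arr)), dim(arr)), 0)
    v <- intensity_volume(arr, c(dz, 25, 25), focal_depth_um = 150)
    fit <- fit_attenuation(v, 0, z_r_um = 1000, mask_rel = 0.03)
    expect_lt(abs(fit$mu_median - mu) / mu, 0.05)
  }

  # an all-zero A-line is flagged invalid, not an error
  arr <- array(rep(model_profile(2), 4), c(length(model_profile(2)), 2, 2))
  arr[, 2, 2] <- 0
  fit <- fit_attenuation(intensity_volume(arr, c(dz, 25, 25), focal_depth_um = 150),
                         0, z_r_um = 1000)
  expect_true(is.na(fit$mu[2, 2]))
  expect_lt(abs(fit$mu_median - 2) / 2, 0.01)

  expect_error(fit_attenuation(as_vol(model_profile(1)[1:10]), 0), "axial samples")
})

test_that("depth compensation flattens the generating model and is idempotent", {
  ls <- fixture_laser()
  dz <- depth_bin_um(ls)
  prof <- model_profile(2, i0 = 0.5)
  v <- intensity_volume(array(rep(prof, 16), c(length(prof), 4, 4)),
                        c(dz, 25, 25), focal_depth_um = 150)
  fit <- fit_attenuation(v, 0, z_r_um = 1000)
  comp <- compensate_depth(v, fit)
  expect_true(all(comp$intensity >= 0))
  flat <- comp$intensity[, 1, 1]
  expect_lt(sd(flat) / mean(flat), 0.01)

  # a second fit on the compensated volume finds mu ~ 0
  fit2 <- fit_attenuation(comp, 0, z_r_um = 1e9)
  expect_lt(fit2$mu_median, 0.01)

  # mu = 0 and a flat confocal envelope leave the volume untouched
  flatv <- intensity_volume(array(1, c(64, 2, 2)), c(dz, 25, 25))
  fit0 <- structure(list(mu = matrix(0, 2, 2), mu_median = 0,
                         i0 = matrix(1, 2, 2), z_f_um = 0, z_r_um = 1e12,
                         surface_z_um = 0, residual = matrix(0, 2, 2)),
                    class = "attenuation_fit")
  expect_equal(compensate_depth(flatv, fit0)$intensity, flatv$intensity,
               tolerance = 1e-12)
})

test_that("focal-stack fusion is a partition of unity favouring the in-focus plane", {
  dz <- 6
  mk <- function(val, z0, zf) intensity_volume(array(val, c(20, 4, 4)),
                                               c(dz, 25, 25), z0_um = z0,
                                               focal_depth_um = zf)
  # single volume: identity
  v <- mk(2, 0, 50)
  expect_identical(fuse_focal_stack(list(v)), v)

  # constant inputs fuse to the same constant (weights sum to one)
  fused <- fuse_focal_stack(list(mk(3, 0, 40), mk(3, 0, 56)))
  expect_equal(range(fused$intensity), c(3, 3), tolerance = 1e-12)

  # the in-focus volume dominates at its own plane by the weight formula:
  # two planes one step apart, sigma = step/2 -> weight 1/(1 + exp(-2))
  w <- focal_fusion_weights(c(40, 56), c(40, 56))
  expect_equal(w[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(w[2, 2], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_gt(w[1, 1], 0.85)
  expect_equal(rowSums(w), c(1, 1), tolerance = 1e-12)

  expect_error(fuse_focal_stack(list(mk(1, 0, 56), mk(1, 0, 40))),
               "increasing")
})
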