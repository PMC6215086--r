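test_that("the stated acquisition geometry gives 125 um isotropic voxels", {
  expect_identical(isotropic_voxel_size_um(c(16, 12, 8), c(128, 96, 64)), 125)
})

test_that("the multishell scheme has 70 volumes of quasi-uniform unit directions", {
  sc <- build_scheme(c(6, 15, 42), c(400, 1066, 2000), n_b0 = 7, seed = 1)
  tab <- sc$table
  expect_equal(nrow(tab), 70L)
  expect_equal(sum(tab$bval == 0), 7L)
  expect_equal(as.vector(table(tab$bval[tab$bval > 0])[c("400", "1066", "2000")]),
               c(6L, 15L, 42L))

  # b0 volumes are interlaced, not clustered
  b0pos <- tab$index[tab$shell == 0]
  expect_gt(min(diff(b0pos)), 5)

  g <- as.matrix(tab[tab$shell > 0, c("gx", "gy", "gz")])
  expect_lt(max(abs(sqrt(rowSums(g^2)) - 1)), 1e-12)
  expect_true(all(tab[tab$shell == 0, c("gx", "gy", "gz")] == 0))

  # per-shell minimum angular separation beats random directions (median
  # over 20 seeds, largest shell)
  rand_min_angle <- function(n) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    d <- v %*% t(v); diag(d) <- -1
    acos(pmin(pmax(max(d[upper.tri(d)]), -1), 1)) * 180 / pi
  }
  set.seed(2)
  ours <- vapply(1:20, function(s) scheme_min_angle(build_scheme(seed = s))[3], 0)
  base <- vapply(1:20, function(s) rand_min_angle(42), 0)
  expect_gt(median(ours), median(base))

  expect_error(build_scheme(c(-1, 5), c(400, 1000)), "negative")
  expect_error(build_scheme(c(6, 15), c(400, 1066, 2000)), "length")
})

test_that("ventricles segment out of the b0 volume at the fluid quantile", {
  ph <- fixture_phantom()
  sc <- build_scheme()
  dwi <- simulate_dwi_series(ph, sc, noise_sd = 0.05, seed = 2)
  b0 <- dwi$signal[, , , 1]

  fluid_q <- 1 - sum(ph$ventricle_mask) / sum(ph$tissue_mask)
  vm <- segment_ventricles(b0, quantile = fluid_q, brain_mask = ph$tissue_mask)
  dice <- 2 * sum(vm & ph$ventricle_mask) / (sum(vm) + sum(ph$ventricle_mask))
  expect_gte(dice, 0.9)
  expect_true(all(vm <= ph$tissue_mask))

  expect_identical(segment_ventricles(b0, quantile = 0,
                                      brain_mask = ph$tissue_mask),
                   ph$tissue_mask)
  expect_error(segment_ventricles(array(1, c(4, 4, 4))), "degenerate")
})

test_that("CSF drift estimation recovers an injected linear drift", {
  ph <- fixture_phantom()
  sc <- build_scheme()
  shell <- sc$table$shell

  # drift-free, noiseless: estimated drift is identically zero
  flat <- simulate_dwi_series(ph, sc, seed = 2)
  e0 <- estimate_drift(flat, ph$ventricle_mask, n_voxels = 200, seed = 3)
  expect_lt(max(abs(e0$drift)), 1e-12)

  # 1% per volume linear drift: recovered within 0.2% of S0 (rms, against
  # the identifiable part of the injected profile)
  d <- 0.01 * (seq_len(70) - 1)
  drifted <- simulate_dwi_series(ph, sc, drift = d, seed = 2)
  est <- estimate_drift(drifted, ph$ventricle_mask, n_voxels = 200, seed = 3)
  amp <- tapply(est$measured / (1 + d), shell, mean)[as.character(shell)]
  truth_id <- unname(amp * (d - ave(d, shell)))
  s0_csf <- mean(est$measured[shell == 0] / (1 + d[shell == 0]))
  expect_lte(sqrt(mean((est$drift - truth_id)^2)) / s0_csf, 0.002)

  # unsmoothed estimation is exact at machine precision when noiseless
  raw <- estimate_drift(drifted, ph$ventricle_mask, n_voxels = 200, sigma_subscan = 0, seed = 3)
  expect_lt(max(abs(raw$drift - truth_id)), 1e-12)

  # estimate is voxel-subset independent within 3 sd(noise)/sqrt(n)
  noisy <- simulate_dwi_series(ph, sc, drift = d, noise_sd = 0.05, seed = 2)
  ea <- estimate_drift(noisy, ph$ventricle_mask, n_voxels = 100, seed = 1)
  eb <- estimate_drift(noisy, ph$ventricle_mask, n_voxels = 100, seed = 2)
  expect_lt(max(abs(ea$drift - eb$drift)), 3 * 0.05 / sqrt(100) * 2)

  expect_error(estimate_drift(flat, array(FALSE, dim(ph$tissue_mask))),
               "empty")
})

test_that("drift compensation flattens per-shell CSF means and conserves them", {
  ph <- fixture_phantom()
  sc <- build_scheme()
  shell <- sc$table$shell
  d <- 0.01 * (seq_len(70) - 1)

  flat <- simulate_dwi_series(ph, sc, seed = 2)
  zero <- estimate_drift(flat, ph$ventricle_mask, n_voxels = 200, seed = 3)
  expect_equal(compensate_drift(flat, zero)$signal, flat$signal,
               tolerance = 1e-12)

  # end-to-end on a noisy drifted series: post-correction per-shell CSF
  # deviations within 2x the drift-free level
  noise <- 0.05
  set.seed(31)
  drifted <- simulate_dwi_series(ph, sc, drift = d, noise_sd = noise, seed = 7)
  ref <- simulate_dwi_series(ph, sc, noise_sd = noise, seed = 7)
  csf <- which(ph$ventricle_mask)
  dev_of <- function(dwi) {
    est <- estimate_drift(dwi, ph$ventricle_mask, n_voxels = 200, seed = 3)
    corr <- compensate_drift(dwi, est)
    cm <- colMeans(matrix(corr$signal, ncol = 70)[csf, ])
    max(abs(cm - ave(cm, shell)))
  }
  expect_lte(dev_of(drifted), 2 * dev_of(ref))

  # with smoothing disabled, compensation preserves per-shell global means
  est0 <- estimate_drift(drifted, ph$ventricle_mask, n_voxels = 200, sigma_subscan = 0, seed = 3)
  corr0 <- compensate_drift(drifted, est0)
  before <- tapply(colMeans(matrix(drifted$signal, ncol = 70)[csf, ]), shell, mean)
  after <- tapply(colMeans(matrix(corr0$signal, ncol = 70)[csf, ]), shell, mean)
  expect_equal(unname(after), unname(before), tolerance = 1e-9)

  # estimate-and-compensate twice: the second pass changes nothing
  once <- compensate_drift(drifted, estimate_drift(drifted, ph$ventricle_mask,
                                                   n_voxels = 200, seed = 3))
  est2 <- estimate_drift(once, ph$ventricle_mask, n_voxels = 200, seed = 3)
  twice <- compensate_drift(once, est2)
  expect_lt(max(abs(twice$signal - once$signal)),
            1e-2 * max(abs(est2$measured)))
})

test_that("NuFO applies the 1.5x ventricle AFD threshold per voxel", {
  out <- nufo_from_peaks(rbind(c(0.5, 0.2, 0.1)), ventricle_afd = 0.1)
  expect_equal(attr(out, "threshold"), 0.15)
  expect_equal(as.integer(out), 2L)

  expect_equal(as.integer(nufo_from_peaks(rbind(c(0.01, 0.02)), 0.1)), 0L)

  # matches a brute-force per-voxel loop on random voxels
  set.seed(14)
  peaks <- matrix(runif(1000 * 4), 1000)
  peaks[sample(length(peaks), 800)] <- NA
  ref <- runif(50, 0.2, 0.4)
  fast <- nufo_from_peaks(peaks, ref)
  thr <- 1.5 * mean(ref)
  slow <- vapply(seq_len(1000), function(v) {
    p <- peaks[v, ]
    sum(p[!is.na(p)] >= thr)
  }, 0L)
  expect_identical(as.integer(fast), slow)

  expect_error(nufo_from_peaks(rbind(c(-0.1, 0.2)), 0.1), "negative")
  expect_error(nufo_from_peaks(rbind(c(0.1)), numeric(0)), "empty")
})
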