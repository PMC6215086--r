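# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function(seed = 7, shape = c(64L, 64L, 32L)) {
  key <- paste0("ph_", seed, "_", paste(shape, collapse = "x"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_phantom(shape = shape, seed = seed)
  .fixtures[[key]]
}

fixture_laser <- function() laser_spec()

# noiseless single-scattering + confocal intensity profile on the depth axis
model_profile <- function(mu_mm1, z_f_um = 150, z_r_um = 1000, i0 = 1,
                          laser = laser_spec()) {
  zax <- depth_axis_um(laser)
  i0 * confocal_factor(zax, z_f_um, z_r_um) * exp(-2 * mu_mm1 * zax * 1e-3)
}

# slice AIP of the phantom with a little acquisition noise
fixture_aip <- function(phantom = fixture_phantom(), z_range = 8:16,
                        noise_sd = 0.02, seed = 21) {
  aip <- apply(phantom$reflectivity[, , z_range], c(1, 2), mean)
  set.seed(seed)
  aip + matrix(rnorm(length(aip), sd = noise_sd), nrow(aip))
}

# brute-force zero-mean NCC scan (independent oracle for match_template)
ncc_brute_force <- function(img, tpl) {
  nr <- nrow(img) - nrow(tpl) + 1L
  nc <- ncol(img) - ncol(tpl) + 1L
  best <- c(NA, NA); bs <- -2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    p <- img[i + seq_len(nrow(tpl)) - 1L, j + seq_len(ncol(tpl)) - 1L]
    s <- suppressWarnings(stats::cor(as.vector(p), as.vector(tpl)))
    if (is.finite(s) && s > bs) { bs <- s; best <- c(i, j) }
  }
  list(pos = best, score = bs)
}

# cut a stack of truth/reconstruction tiles for the end-to-end reassembly
# (serial sectioning of the phantom: 3 x 3 tile raster per slice)
build_serial_acquisition <- function(phantom, slice_z_um = c(0, 200, 400),
                                     imaging_bins = 47L, seed = 100L) {
  ts <- tile_spec()
  ls <- laser_spec()
  grid <- tile_raster(0, 0, 3, 3, ts)
  recon_slices <- truth_slices <- vector("list", length(slice_z_um))
  for (s in seq_along(slice_z_um)) {
    rtiles <- ttiles <- vector("list", nrow(grid))
    for (t in seq_len(nrow(grid))) {
      pl <- tile_placement(grid$x0_um[t], grid$y0_um[t],
                           z0_um = slice_z_um[s], focal_depth_um = slice_z_um[s])
      ft <- simulate_tile_fringes(phantom, pl, ts, ls,
                                  seed = seed + s * 100L + t)
      rv <- reconstruct_tile(ft)
      crop <- function(a) a[seq_len(imaging_bins), , , drop = FALSE]
      rtiles[[t]] <- intensity_volume(crop(rv$intensity), rv$voxel_size_um,
                                      rv$origin_um, z0_um = 0,
                                      focal_depth_um = rv$focal_depth_um)
      ttiles[[t]] <- intensity_volume(crop(ft$truth), rv$voxel_size_um,
                                      rv$origin_um, z0_um = 0,
                                      focal_depth_um = rv$focal_depth_um)
    }
    recon_slices[[s]] <- stitch_slice(rtiles, slice_index = s - 1L,
                                      z_position_um = slice_z_um[s])
    truth_slices[[s]] <- stitch_slice(ttiles, slice_index = s - 1L,
                                      z_position_um = slice_z_um[s])
  }
  list(recon = recon_slices, truth = truth_slices)
}
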