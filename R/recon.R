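# Fringe-to-intensity reconstruction, attenuation compensation and
# dynamic-focus fusion.

#' Intensity volume container
#'
#' @param intensity 3-D nonnegative array, z x fast-axis x slow-axis.
#' @param voxel_size_um Length-3 voxel size (z, x, y) in um.
#' @param origin_um Cartesian (x, y) position of the volume's lower corner.
#' @param z0_um Depth of the first axial bin (um).
#' @param focal_depth_um Focal-plane depth (um).
#' @export
intensity_volume <- function(intensity, voxel_size_um, origin_um = c(0, 0),
                             z0_um = 0, focal_depth_um = 0) {
  stop_if(any(!is.finite(intensity)), "intensity must be finite")
  stop_if(any(intensity < 0), "intensity must be nonnegative")
  structure(list(intensity = intensity, voxel_size_um = voxel_size_um,
                 origin_um = origin_um, z0_um = z0_um,
                 focal_depth_um = focal_depth_um),
            class = "intensity_volume")
}

#' Reconstruct one A-line from a raw fringe
#'
#' Subtracts the reference fringe, multiplies by the Gaussian spectral
#' apodization window (expressed in wavelength and resampled onto the k-grid),
#' inverse Fourier transforms, and keeps the first half of the axial range
#' (the second half duplicates it by Hermitian symmetry of real signals). The
#' magnitude is squared to intensity and scaled so that a cosine fringe of
#' amplitude `a` at an unattenuated window reconstructs to intensity `a^2`.
#'
#' @param fringe Real fringe samples (length `n_k_samples`).
#' @param reference Reference fringe of the same length.
#' @param laser A [laser_spec()].
#' @return Intensity profile of length `n_k_samples / 2`; depths given by
#'   [depth_axis_um()].
#' @export
reconstruct_aline <- function(fringe, reference, laser = laser_spec()) {
  stop_if(length(fringe) != length(reference),
          "fringe and reference lengths differ")
  stop_if(length(fringe) != laser$n_k_samples,
          "fringe length does not match laser n_k_samples")
  w <- apodization_window(laser)
  a <- stats::fft((fringe - reference) * w, inverse = TRUE) / length(fringe)
  4 * Mod(a[seq_len(length(fringe) %/% 2L)])^2
}

#' Reconstruct a fringe tile into an intensity volume
#'
#' The reference fringe is the average fringe over all lateral positions of
#' the tile (computed from the data, per acquisition); every A-line is then
#' reconstructed with [reconstruct_aline()].
#'
#' @param tile A `fringe_tile`.
#' @param reference Optional explicit reference fringe; default is the tile
#'   mean.
#' @return An [intensity_volume()] with the tile's placement metadata.
#' @export
reconstruct_tile <- function(tile, reference = NULL) {
  fr <- tile$fringes
  stop_if(any(!is.finite(fr)), "non-finite fringe data")
  d <- dim(fr)
  stop_if(is.null(d) || length(d) != 3L, "fringes must be a 3-D array")
  n <- d[1]
  m <- matrix(fr, nrow = n)
  reference <- reference %||% rowMeans(m)
  laser <- tile$laser
  w <- apodization_window(laser)
  x <- (m - reference) * w
  a <- stats::mvfft(x, inverse = TRUE) / n
  intens <- 4 * Mod(a[seq_len(n %/% 2L), , drop = FALSE])^2
  pitch <- tile$pitch_um %||% (tile$tile$fov_mm * 1000 / d[2])
  intensity_volume(array(intens, c(n %/% 2L, d[2], d[3])),
                   voxel_size_um = c(depth_bin_um(laser), pitch, pitch),
                   origin_um = c(tile$placement$x0_um, tile$placement$y0_um),
                   z0_um = tile$placement$z0_um,
                   focal_depth_um = tile$placement$focal_depth_um)
}

#' Fit the single-scattering + confocal attenuation model
#'
#' Per A-line least squares of `I(z) = i0 * T(z) * exp(-2 mu (z - zs))` on
#' log-intensity, with the confocal envelope
#' `T(z) = (((z - z_f)/z_r)^2 + 1)^-1` held at its known system values.
#' Fitting in the log domain keeps the problem linear; voxels below
#' `mask_rel` times the volume maximum are excluded, and A-lines with fewer
#' than `min_samples` usable voxels below the surface are flagged invalid
#' (NA) and excluded from the tile median.
#'
#' @param vol An [intensity_volume()].
#' @param tissue_surface_z_um Depth of the tissue surface (um, absolute frame
#'   of the volume's z axis).
#' @param z_f_um Focal depth; defaults to the volume's metadata.
#' @param z_r_um Apparent Rayleigh range of the confocal envelope (um).
#' @param mask_rel Relative intensity floor for usable voxels.
#' @param min_samples Minimum axial samples required below the surface.
#' @return An object of class `attenuation_fit`: per-A-line `mu` (mm^-1,
#'   matrix), `mu_median`, `i0`, `z_f_um`, `z_r_um`, `surface_z_um`,
#'   `residual` (rms log-intensity).
#' @export
fit_attenuation <- function(vol, tissue_surface_z_um = 0,
                            z_f_um = vol$focal_depth_um, z_r_um = 1000,
                            mask_rel = 1e-6, min_samples = 16L) {
  d <- dim(vol$intensity)
  z <- vol$z0_um + (seq_len(d[1]) - 1L) * vol$voxel_size_um[1]
  below <- z >= tissue_surface_z_um
  stop_if(sum(below) < min_samples,
          sprintf("need >= %d axial samples below the surface", min_samples))
  tz <- confocal_factor(z, z_f_um, z_r_um)
  imax <- max(vol$intensity)
  nlat <- d[2] * d[3]
  m <- matrix(vol$intensity, nrow = d[1])
  mu <- i0 <- resid <- rep(NA_real_, nlat)
  zmm <- (z - tissue_surface_z_um) * 1e-3   # mm below surface
  for (j in seq_len(nlat)) {
    y <- m[, j]
    use <- below & y > mask_rel * imax
    if (sum(use) < min_samples) next
    ly <- log(y[use]) - log(tz[use])
    zz <- zmm[use]
    # intensity-squared weights: var(log(I + n)) ~ (sd(n)/I)^2, so weighting
    # by I^2 is the usual fix for the low-signal bias of log-linear fits
    w <- y[use]^2
    w <- w / sum(w)
    zb <- sum(w * zz); lb <- sum(w * ly)
    vz <- sum(w * (zz - zb)^2)
    if (vz <= 0) next
    slope <- sum(w * (zz - zb) * (ly - lb)) / vz
    icpt <- lb - slope * zb
    mu[j] <- max(0, -slope / 2)
    i0[j] <- exp(icpt)
    resid[j] <- sqrt(sum(w * (ly - (icpt + slope * zz))^2))
  }
  structure(list(mu = matrix(mu, d[2], d[3]), mu_median = stats::median(mu, na.rm = TRUE),
                 i0 = matrix(i0, d[2], d[3]), z_f_um = z_f_um, z_r_um = z_r_um,
                 surface_z_um = tissue_surface_z_um,
                 residual = matrix(resid, d[2], d[3])),
            class = "attenuation_fit")
}

#' Compensate depth-dependent contrast using a fitted attenuation model
#'
#' Divides the intensity by `T(z) * exp(-2 mu (z - surface))` at and below the
#' tissue surface; voxels above the surface are untouched. Per-A-line `mu`
#' estimates are used where valid, the tile median elsewhere.
#'
#' @param vol An [intensity_volume()].
#' @param fit An [fit_attenuation()] result for this volume.
#' @return A compensated [intensity_volume()].
#' @export
compensate_depth <- function(vol, fit) {
  d <- dim(vol$intensity)
  stop_if(!all(dim(fit$mu) == d[2:3]), "fit does not match this volume")
  z <- vol$z0_um + (seq_len(d[1]) - 1L) * vol$voxel_size_um[1]
  below <- z >= fit$surface_z_um
  tz <- confocal_factor(z, fit$z_f_um, fit$z_r_um)
  zmm <- pmax(z - fit$surface_z_um, 0) * 1e-3
  mu <- as.vector(fit$mu)
  mu[!is.finite(mu)] <- fit$mu_median
  if (!is.finite(fit$mu_median)) mu[] <- 0
  m <- matrix(vol$intensity, nrow = d[1])
  fac <- outer(tz, rep(1, ncol(m))) * exp(outer(-2 * zmm, mu))
  fac[!below, ] <- 1
  out <- m / fac
  intensity_volume(array(out, d), vol$voxel_size_um, vol$origin_um,
                   vol$z0_um, vol$focal_depth_um)
}

#' Fuse a dynamic-focus stack into one OCM volume
#'
#' Depth-weighted average with Gaussian weights centred on each volume's
#' focal plane (sigma = half the focal-plane spacing), normalized so the
#' weights of all contributing volumes sum to one at every depth. The output
#' axial range spans the union of the input ranges; each input is linearly
#' resampled onto that axis and contributes zero weight where it has no data.
#'
#' @param vols List of [intensity_volume()] with strictly increasing focal
#'   depths and a common depth-bin spacing.
#' @return A fused [intensity_volume()] (focal depth = mean of the stack).
#' @export
fuse_focal_stack <- function(vols) {
  stop_if(length(vols) < 1, "need at least one volume")
  if (length(vols) == 1L) return(vols[[1]])
  zf <- vapply(vols, function(v) v$focal_depth_um, 0)
  stop_if(any(diff(zf) <= 0), "focal depths must be strictly increasing")
  dz <- vols[[1]]$voxel_size_um[1]
  stop_if(any(abs(vapply(vols, function(v) v$voxel_size_um[1], 0) - dz) > 1e-9),
          "volumes must share the depth-bin spacing")
  z0 <- min(vapply(vols, function(v) v$z0_um, 0))
  z1 <- max(vapply(vols, function(v) v$z0_um + (dim(v$intensity)[1] - 1) * dz, 0))
  zax <- seq(z0, z1, by = dz)
  sigma <- mean(diff(zf)) / 2
  d2 <- dim(vols[[1]]$intensity)[2:3]
  acc <- array(0, c(length(zax), d2))
  wsum <- numeric(length(zax))
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    nzv <- dim(v$intensity)[1]
    idx <- (zax - v$z0_um) / dz + 1
    cover <- idx >= 1 & idx <= nzv
    w <- exp(-(zax - zf[i])^2 / (2 * sigma^2)) * cover
    m <- matrix(v$intensity, nrow = nzv)
    lo <- pmin(pmax(floor(idx), 1L), nzv); t <- pmin(pmax(idx - lo, 0), 1)
    hi <- pmin(lo + 1L, nzv)
    res <- (1 - t) * m[lo, , drop = FALSE] + t * m[hi, , drop = FALSE]
    acc <- acc + array(w * res, c(length(zax), d2))
    wsum <- wsum + w
  }
  ok <- wsum > 0
  acc[ok, , ] <- acc[ok, , , drop = FALSE] / wsum[ok]
  intensity_volume(acc, vols[[1]]$voxel_size_um, vols[[1]]$origin_um,
                   z0_um = z0, focal_depth_um = mean(zf))
}

# normalized fusion weight of volume i at depth z (for auditing the blend)
focal_fusion_weights <- function(focal_depths_um, z_um) {
  sigma <- mean(diff(focal_depths_um)) / 2
  w <- vapply(focal_depths_um, function(f) exp(-(z_um - f)^2 / (2 * sigma^2)), numeric(length(z_um)))
  w <- matrix(w, nrow = length(z_um))
  w / rowSums(w)
}

#' Measured axial PSF width of the system
#'
#' Simulates a mirror (single reflector) at the given depth, reconstructs it
#' through the apodized pipeline and returns the full width at half maximum of
#' the intensity peak (um), by linear interpolation of the half-maximum
#' crossings.
#'
#' @param laser A [laser_spec()].
#' @param z0_um Mirror depth (um).
#' @return FWHM in um.
#' @export
measure_axial_psf_fwhm <- function(laser = laser_spec(), z0_um = 200) {
  kk <- k_grid(laser)
  fringe <- cos(2 * kk * laser$n_medium * z0_um * 1e3)  # k in nm^-1, z in nm
  prof <- reconstruct_aline(fringe, rep(0, length(fringe)), laser)
  zax <- depth_axis_um(laser)
  pk <- which.max(prof)
  half <- prof[pk] / 2
  left <- right <- NA_real_
  for (i in seq(pk, 2)) if (prof[i - 1] < half) {
    t <- (half - prof[i - 1]) / (prof[i] - prof[i - 1])
    left <- zax[i - 1] + t * (zax[i] - zax[i - 1]); break
  }
  for (i in seq(pk, length(prof) - 1)) if (prof[i + 1] < half) {
    t <- (prof[i] - half) / (prof[i] - prof[i + 1])
    right <- zax[i] + t * (zax[i + 1] - zax[i]); break
  }
  right - left
}
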