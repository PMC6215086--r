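# Swept-source geometry shared by the fringe simulator and the reconstruction.
#
# Conventions (used consistently everywhere):
#   * x, y are lateral stage-plane coordinates, z is depth into the tissue;
#     all physical lengths are micrometres unless a name says otherwise.
#   * Fringes are sampled on a k-grid linear in wavenumber k = 2*pi/lambda.
#   * A reflector at depth z in a medium of refractive index n contributes
#     sqrt(I) * cos(2 k n z) to the fringe; the conjugate depth-bin spacing is
#     therefore dz = pi / ((k_max - k_min) * n).

#' Swept-source laser specification
#'
#' Describes the swept source used for both imaging arms: a central wavelength
#' of 1310 nm with a 100 nm tuning bandwidth, sampled at `n_k_samples` points
#' linear in wavenumber, and the Gaussian spectral apodization window applied
#' before the inverse Fourier transform.
#'
#' @param lambda0_nm Central wavelength (nm).
#' @param tuning_bandwidth_nm Full sweep bandwidth (nm).
#' @param n_k_samples Number of k-linear samples per fringe (even).
#' @param apod_mu_nm,apod_sigma_nm Centre and width of the Gaussian
#'   apodization window, expressed in wavelength (nm).
#' @param n_medium Refractive index used for the depth calibration (water).
#' @return An object of class `laser_spec`.
#' @export
laser_spec <- function(lambda0_nm = 1310, tuning_bandwidth_nm = 100,
                       n_k_samples = 256L, apod_mu_nm = 1310,
                       apod_sigma_nm = 20, n_medium = 1.33) {
  stop_if(apod_sigma_nm <= 0, "apod_sigma_nm must be > 0")
  stop_if(n_k_samples < 8 || n_k_samples %% 2 != 0,
          "n_k_samples must be an even integer >= 8")
  stop_if(tuning_bandwidth_nm <= 0 || lambda0_nm <= tuning_bandwidth_nm / 2,
          "invalid wavelength sweep")
  structure(list(lambda0_nm = lambda0_nm,
                 tuning_bandwidth_nm = tuning_bandwidth_nm,
                 n_k_samples = as.integer(n_k_samples),
                 apod_mu_nm = apod_mu_nm, apod_sigma_nm = apod_sigma_nm,
                 n_medium = n_medium),
            class = "laser_spec")
}

#' Tile acquisition geometry
#'
#' Lateral field of view, overlap fraction between neighbouring mosaic tiles,
#' lateral sampling, slice thickness and the axial stepping used by the
#' dynamic-focus (OCM) and interface-scout acquisitions.
#'
#' @param fov_mm Lateral tile field of view (mm, square tiles).
#' @param overlap_fraction Overlap fraction between adjacent tiles in [0, 1).
#' @param n_lat Lateral samples per axis within a tile.
#' @param slice_thickness_um Vibratome slice thickness (um).
#' @param ocm_z_step_um Axial spacing of consecutive focal planes in a
#'   dynamic-focus stack (um).
#' @param interface_scan_step_um Axial spacing of the coarse interface-finding
#'   scan (um).
#' @param z_rayleigh_um Apparent Rayleigh range of the objective's confocal
#'   axial envelope (um); the low-magnification arm has a long depth of focus.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(fov_mm = 0.5, overlap_fraction = 0.2, n_lat = 20L,
                      slice_thickness_um = 200, ocm_z_step_um = 16,
                      interface_scan_step_um = 50, z_rayleigh_um = 1000) {
  stop_if(overlap_fraction < 0 || overlap_fraction >= 1,
          "overlap_fraction must be in [0, 1)")
  stop_if(fov_mm <= 0, "fov_mm must be > 0")
  stride <- fov_mm * (1 - overlap_fraction)
  stop_if(stride <= 0, "tile stride must be > 0")
  structure(list(fov_mm = fov_mm, overlap_fraction = overlap_fraction,
                 n_lat = as.integer(n_lat),
                 slice_thickness_um = slice_thickness_um,
                 ocm_z_step_um = ocm_z_step_um,
                 interface_scan_step_um = interface_scan_step_um,
                 z_rayleigh_um = z_rayleigh_um,
                 stride_mm = stride),
            class = "tile_spec")
}

#' Linear wavenumber grid of a sweep (nm^-1, strictly increasing)
#' @param laser A [laser_spec()].
#' @export
k_grid <- function(laser) {
  lmin <- laser$lambda0_nm - laser$tuning_bandwidth_nm / 2
  lmax <- laser$lambda0_nm + laser$tuning_bandwidth_nm / 2
  seq(2 * pi / lmax, 2 * pi / lmin, length.out = laser$n_k_samples)
}

#' Depth-bin spacing of the reconstructed A-line (um)
#'
#' dz = pi / ((k_max - k_min) * n_medium): the spacing of the discrete depth
#' bins conjugate to a fringe of the form cos(2 k n z).
#' @param laser A [laser_spec()].
#' @export
depth_bin_um <- function(laser) {
  kk <- k_grid(laser)
  (pi / ((kk[length(kk)] - kk[1]) * laser$n_medium)) / 1e3
}

#' Depth axis of a reconstructed half-range A-line (um)
#' @param laser A [laser_spec()].
#' @export
depth_axis_um <- function(laser) {
  (seq_len(laser$n_k_samples / 2) - 1L) * depth_bin_um(laser)
}

#' Gaussian apodization weight at given wavelengths
#'
#' Peak-normalized Gaussian window in wavelength: weight 1 at `apod_mu_nm`,
#' exp(-1/2) one sigma away.
#' @param lambda_nm Wavelengths (nm).
#' @param laser A [laser_spec()].
#' @export
apodization_weight <- function(lambda_nm, laser) {
  exp(-(lambda_nm - laser$apod_mu_nm)^2 / (2 * laser$apod_sigma_nm^2))
}

# window sampled on the k-grid (expressed in wavelength, resampled to k)
apodization_window <- function(laser) {
  apodization_weight(2 * pi / k_grid(laser), laser)
}

#' Confocal axial point-spread envelope
#'
#' The standard single-mode axial sensitivity factor
#' T(z) = 1 / (((z - z_f) / z_r)^2 + 1), peaking at the focal depth `z_f` with
#' apparent Rayleigh range `z_r`.
#' @param z_um Depths (um).
#' @param z_f_um Focal depth (um).
#' @param z_r_um Apparent Rayleigh range (um).
#' @export
confocal_factor <- function(z_um, z_f_um, z_r_um) {
  stop_if(any(z_r_um <= 0), "z_r_um must be > 0")
  1 / (((z_um - z_f_um) / z_r_um)^2 + 1)
}
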