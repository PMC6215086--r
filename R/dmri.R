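# Multishell gradient-scheme handling, the CSF-anchored signal-drift
# compensation for ex vivo acquisitions, and the data-driven NuFO threshold.

#' Isotropic voxel size implied by a field of view and acquisition matrix
#'
#' @param fov_mm Field of view per axis (mm).
#' @param matrix_dim Acquisition matrix per axis.
#' @return Voxel size in um; a scalar when isotropic, else one value per axis.
#' @export
isotropic_voxel_size_um <- function(fov_mm = c(16, 12, 8),
                                    matrix_dim = c(128, 96, 64)) {
  stop_if(length(fov_mm) != length(matrix_dim), "axis counts differ")
  v <- fov_mm * 1000 / matrix_dim
  if (max(v) - min(v) < 1e-9) v[1] else v
}

# deterministic quasi-uniform unit directions (spiral / Fibonacci sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  ga <- pi * (3 - sqrt(5))
  th <- i * ga
  d <- cbind(r * cos(th), r * sin(th), z)
  d / sqrt(rowSums(d^2))
}

# seeded proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a multishell gradient scheme
#'
#' Quasi-uniform unit directions per shell from a seeded, randomly rotated
#' Fibonacci-sphere construction, with the b = 0 volumes interlaced evenly
#' across the acquisition order. The default scheme is the 70-volume ex vivo
#' protocol: 6 directions at b = 400, 15 at b = 1066, 42 at b = 2000 s/mm^2
#' and 7 interleaved b = 0 acquisitions.
#'
#' @param n_per_shell Directions per shell.
#' @param b_values Shell b-values (s/mm^2), same length.
#' @param n_b0 Number of b = 0 volumes.
#' @param seed Integer seed for the shell rotations.
#' @return An object of class `gradient_scheme` with `table` (data frame:
#'   `index`, `bval`, `gx`, `gy`, `gz`, `shell`; shell 0 is b = 0) and
#'   `b_values`.
#' @export
build_scheme <- function(n_per_shell = c(6L, 15L, 42L),
                         b_values = c(400, 1066, 2000), n_b0 = 7L, seed = 1L) {
  stop_if(length(n_per_shell) != length(b_values), "lists must have same length")
  stop_if(any(n_per_shell < 0) || n_b0 < 0, "negative counts")
  with_seed(seed, {
    dwi <- do.call(rbind, lapply(seq_along(n_per_shell), function(s) {
      d <- fibonacci_sphere(n_per_shell[s]) %*% random_rotation()
      data.frame(bval = b_values[s], gx = d[, 1], gy = d[, 2], gz = d[, 3],
                 shell = s)
    }))
    total <- nrow(dwi) + n_b0
    b0_at <- if (n_b0 > 0) unique(round(seq(1, total, length.out = max(n_b0, 1)))) else integer(0)
    tab <- data.frame(bval = numeric(total), gx = 0, gy = 0, gz = 0,
                      shell = 0L)
    tab[setdiff(seq_len(total), b0_at), ] <- dwi
    tab$index <- seq_len(total)
    structure(list(table = tab[, c("index", "bval", "gx", "gy", "gz", "shell")],
                   b_values = b_values, n_b0 = n_b0, seed = seed),
              class = "gradient_scheme")
  })
}

#' Minimum angular separation within each shell (degrees)
#' @param scheme A [build_scheme()].
#' @export
scheme_min_angle <- function(scheme) {
  tab <- scheme$table
  vapply(sort(unique(tab$shell[tab$shell > 0])), function(s) {
    g <- as.matrix(tab[tab$shell == s, c("gx", "gy", "gz")])
    if (nrow(g) < 2) return(NA_real_)
    d <- g %*% t(g)
    diag(d) <- -1
    acos(pmin(pmax(max(d[upper.tri(d)]), -1), 1)) * 180 / pi
  }, 0)
}

#' Segment ventricles by thresholding the b0 intensity
#'
#' Fluid is by far the brightest compartment in these long-TE ex vivo b0
#' volumes; voxels above the stated intensity quantile (within the brain
#' mask when given) are labeled ventricle/CSF.
#'
#' @param b0 3-D b = 0 volume.
#' @param quantile Intensity quantile in [0, 1) (0 returns the whole mask).
#' @param brain_mask Optional logical array.
#' @return Logical array.
#' @export
segment_ventricles <- function(b0, quantile = 0.99, brain_mask = NULL) {
  stop_if(diff(range(b0)) <= 0, "degenerate input: constant b0")
  dom <- if (is.null(brain_mask)) array(TRUE, dim(b0)) else brain_mask
  thr <- stats::quantile(b0[dom], quantile, names = FALSE)
  mask <- b0 >= thr & dom
  if (quantile == 0) mask <- dom
  stop_if(!any(mask), "empty ventricle mask")
  mask
}

#' Estimate the temporal signal drift from the CSF
#'
#' Computes the average signal time profile over `n_voxels` voxels drawn at
#' random from the segmented ventricles; builds the synthetic multishell
#' isotropic profile (the per-shell mean of the measured profile, constant
#' within each shell); subtracts it from the measured profile; and smooths
#' the result temporally with a Gaussian of `sigma_subscan` volumes.
#'
#' By default the smoothing runs within each shell (Gaussian weights on
#' acquisition-index distance, restricted to same-shell volumes): the drift
#' excess is scaled by each shell's CSF signal amplitude, and smoothing
#' across shell boundaries would mix values on very different scales.
#' `per_shell = FALSE` gives the plain temporal filter.
#'
#' @param dwi A [simulate_dwi_series()] (or compatible) series.
#' @param csf_mask Logical array of ventricle voxels.
#' @param n_voxels CSF voxels to sample (all, with a warning, if fewer).
#' @param sigma_subscan Temporal Gaussian sigma in volumes (0 = none).
#' @param per_shell Restrict smoothing to same-shell volumes.
#' @param seed Integer seed for the voxel draw.
#' @return An object of class `drift_profile`: `drift` (per volume, signal
#'   units), `raw`, `measured`, `synthetic`, `shell`, `n_voxels`, `seed`.
#' @export
estimate_drift <- function(dwi, csf_mask, n_voxels = 1000L, sigma_subscan = 1,
                           per_shell = TRUE, seed = 1L) {
  stop_if(!any(csf_mask), "empty CSF mask")
  idx <- which(csf_mask)
  if (length(idx) < n_voxels) {
    warning("CSF mask has ", length(idx), " voxels < n_voxels; using all")
    sel <- idx
  } else {
    sel <- with_seed(seed, idx[sample.int(length(idx), n_voxels)])
  }
  sig <- dwi$signal
  d <- dim(sig)
  nv <- d[4]
  m <- matrix(sig, ncol = nv)
  measured <- colMeans(m[sel, , drop = FALSE])
  shell <- dwi$scheme$table$shell
  synthetic <- stats::ave(measured, shell)
  raw <- measured - synthetic
  drift <- raw
  if (sigma_subscan > 0) {
    t_idx <- seq_len(nv)
    if (per_shell) {
      for (s in unique(shell)) {
        in_s <- which(shell == s)
        K <- exp(-outer(t_idx[in_s], t_idx[in_s], "-")^2 / (2 * sigma_subscan^2))
        drift[in_s] <- as.numeric(K %*% raw[in_s] / rowSums(K))
      }
    } else {
      K <- exp(-outer(t_idx, t_idx, "-")^2 / (2 * sigma_subscan^2))
      drift <- as.numeric(K %*% raw / rowSums(K))
    }
  }
  structure(list(drift = drift, raw = raw, measured = measured,
                 synthetic = synthetic, shell = shell,
                 sigma_subscan = sigma_subscan, per_shell = per_shell,
                 n_voxels = length(sel), seed = seed),
            class = "drift_profile")
}

#' Remove the estimated drift from a DWI series
#'
#' Subtracts the per-volume drift excess (the measured-minus-synthetic bias)
#' from every voxel, so post-correction per-shell CSF means are constant
#' across volumes up to noise. A multiplicative variant divides by the
#' fractional excess instead.
#'
#' @param dwi A DWI series.
#' @param drift A [estimate_drift()] profile (length = number of volumes).
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @return The corrected series.
#' @export
compensate_drift <- function(dwi, drift, mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  dvec <- if (inherits(drift, "drift_profile")) drift$drift else drift
  nv <- dim(dwi$signal)[4]
  stop_if(length(dvec) != nv, "drift length must match the number of volumes")
  out <- dwi
  if (mode == "additive") {
    for (v in seq_len(nv)) out$signal[, , , v] <- dwi$signal[, , , v] - dvec[v]
  } else {
    syn <- if (inherits(drift, "drift_profile")) drift$synthetic else
      stop("multiplicative mode needs a drift_profile")
    frac <- 1 + dvec / pmax(syn, .Machine$double.eps)
    for (v in seq_len(nv)) out$signal[, , , v] <- dwi$signal[, , , v] / frac[v]
  }
  out
}

#' Number of fiber orientations from fODF peak amplitudes
#'
#' Applies the data-driven rule: the threshold is 1.5 times the mean
#' apparent-fiber-density reference measured in the ventricles, and NuFO is
#' the number of peaks at or above it.
#'
#' @param peak_amplitudes Matrix (voxels x max peaks; pad with NA) or a list
#'   of per-voxel amplitude vectors; all amplitudes >= 0.
#' @param ventricle_afd Nonempty reference AFD_max values from the ventricles.
#' @return Integer NuFO per voxel; attribute `threshold`.
#' @export
nufo_from_peaks <- function(peak_amplitudes, ventricle_afd) {
  stop_if(length(ventricle_afd) == 0, "empty ventricle reference")
  if (is.list(peak_amplitudes)) {
    mx <- max(vapply(peak_amplitudes, length, 0L), 1L)
    peak_amplitudes <- t(vapply(peak_amplitudes, function(p)
      c(p, rep(NA_real_, mx - length(p))), numeric(mx)))
  }
  pm <- rbind(peak_amplitudes)
  stop_if(any(pm < 0, na.rm = TRUE), "negative peak amplitudes")
  thr <- 1.5 * mean(ventricle_afd)
  out <- as.integer(rowSums(pm >= thr, na.rm = TRUE))
  attr(out, "threshold") <- thr
  out
}

# NODDI configuration metadata used by the fitted maps this package consumes
# (the fitting itself is done with established diffusion tools).
noddi_config <- function() {
  list(d_iso_mm2_s = 1.0e-3, d_parallel_mm2_s = 0.6e-3,
       lambda1 = 0.5, lambda2 = 1.0e-3, ex_vivo = TRUE)
}
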