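# Seeded digital tissue phantom and forward simulators.
#
# The phantom stands in for an agarose-embedded ex vivo mouse brain: an
# ellipsoidal "brain" with layered cortical reflectivity, bright fiber-bundle
# ribbons (one pair crossing), dark tubular vessels, a ventricle, and a toy
# atlas whose fiber-ribbon labels are flagged as the "fiber tracts" ontology
# subset. Every simulator is deterministic given its seed.

#' Generate a seeded digital tissue phantom
#'
#' Builds ground-truth 3-D reflectivity and attenuation volumes together with
#' tissue/fiber/vessel/ventricle masks and a toy atlas label volume. Arrays
#' are indexed `[x, y, z]` with z increasing into the tissue; physical
#' coordinates are micrometres with voxel centers at `(i - 0.5) * voxel_size`.
#'
#' Optical properties are plausible ex vivo values (attenuation in
#' 0.1--5 mm^-1, higher inside fiber bundles than in gray matter).
#'
#' @param shape Integer triple of voxel counts (>= 16 per axis).
#' @param voxel_size_um Isotropic voxel size (um).
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @return An object of class `phantom`: list with elements `reflectivity`,
#'   `attenuation` (mm^-1), `tissue_mask`, `fiber_mask`, `vessel_mask`,
#'   `ventricle_mask`, `crossing_mask`, `agarose_mask`, `atlas_labels`,
#'   `fiber_tract_labels`, `voxel_size_um`, `seed`.
#' @export
make_phantom <- function(shape = c(64L, 64L, 32L), voxel_size_um = 25, seed = 1L) {
  shape <- as.integer(shape)
  stop_if(length(shape) != 3L || any(shape < 16L),
          "`shape` must be a triple of voxel counts >= 16")
  stop_if(voxel_size_um <= 0, "voxel_size_um must be > 0")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.42 * nx; ay <- 0.42 * ny; az <- 0.46 * nz
  ii <- slice.index(array(0, shape), 1)
  jj <- slice.index(array(0, shape), 2)
  kk <- slice.index(array(0, shape), 3)
  e <- ((ii - cx) / ax)^2 + ((jj - cy) / ay)^2 + ((kk - cz) / az)^2

  tissue <- e <= 1
  agarose <- e <= 1.45 & !tissue

  with_seed(seed, {
    # layered cortical reflectivity: layers follow the ellipsoidal shells,
    # modulated by a smooth seeded texture field
    layers <- 0.30 + 0.08 * cos(2 * pi * 5 * sqrt(pmax(e, 0)))
    texture <- gauss_smooth(array(stats::rnorm(prod(shape)), shape), 1.5)
    texture <- texture / max(stats::sd(texture), 1e-12)
    refl <- layers * (1 + 0.15 * texture)

    att <- array(0, shape)
    att[tissue] <- 1.2
    att[agarose] <- 0.3

    # two fiber ribbons, running along x and along y, crossing in the middle
    fib1 <- tissue & abs(jj - 0.62 * ny) < 0.06 * ny & abs(kk - cz) < 0.12 * nz
    fib2 <- tissue & abs(ii - 0.42 * nx) < 0.06 * nx & abs(kk - cz) < 0.12 * nz
    fiber <- fib1 | fib2
    crossing <- fib1 & fib2
    refl[fiber] <- 0.75 * (1 + 0.08 * texture[fiber])
    att[fiber] <- 5.0

    # dark tubular vessels along x at seeded lateral positions
    vessel <- array(FALSE, shape)
    n_vessels <- 3L
    vy <- stats::runif(n_vessels, 0.25, 0.75) * ny
    vz <- stats::runif(n_vessels, 0.30, 0.70) * nz
    for (v in seq_len(n_vessels)) {
      tube <- ((jj - vy[v])^2 + (kk - vz[v])^2) <= 1.5^2
      vessel <- vessel | (tube & tissue)
    }
    vessel <- vessel & !fiber
    refl[vessel] <- 0.04
    att[vessel] <- 0.2

    # one ventricle: dark, fluid-filled
    vent <- (((ii - cx - 0.16 * nx) / (0.10 * nx))^2 +
               ((jj - cy - 0.10 * ny) / (0.10 * ny))^2 +
               ((kk - cz) / (0.16 * nz))^2) <= 1
    vent <- vent & tissue & !fiber
    refl[vent] <- 0.02
    att[vent] <- 0.1

    refl[agarose] <- 0.05 * (1 + 0.1 * texture[agarose])
    refl[!tissue & !agarose] <- 0
    att[!tissue & !agarose] <- 0
    refl <- pmin(pmax(refl, 0), 1)

    # toy atlas: 4 gray-matter quadrant labels, ventricle, two fiber labels
    labels <- array(0L, shape)
    quad <- 1L + (ii > cx) + 2L * (jj > cy)
    labels[tissue] <- quad[tissue]
    labels[vent] <- 5L
    labels[fib1] <- 6L
    labels[fib2] <- 7L
    labels[crossing] <- 7L

    structure(list(
      reflectivity = refl, attenuation = att,
      tissue_mask = tissue, fiber_mask = fiber, vessel_mask = vessel,
      ventricle_mask = vent, crossing_mask = crossing, agarose_mask = agarose,
      atlas_labels = labels, fiber_tract_labels = c(6L, 7L),
      voxel_size_um = rep(voxel_size_um, 3L), shape = shape, seed = seed
    ), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d x %d voxels @ %g um, seed %d\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_um[1], x$seed))
  cat(sprintf("  tissue %.0f%%, fiber %.0f%%, labels %s (fiber tracts: %s)\n",
              100 * mean(x$tissue_mask), 100 * mean(x$fiber_mask),
              paste(sort(unique(as.integer(x$atlas_labels[x$atlas_labels > 0]))),
                    collapse = ","),
              paste(x$fiber_tract_labels, collapse = ",")))
  invisible(x)
}

#' Tile placement descriptor
#'
#' @param x0_um,y0_um Cartesian position of the tile's lower corner (um).
#' @param z0_um Depth of the first axial bin below the block face (um);
#'   for serial sectioning this is the current slice's top surface.
#' @param focal_depth_um Focal-plane depth (um, same frame as `z0_um`).
#' @param microsteps Optional raw stage microstep pair as recorded.
#' @export
tile_placement <- function(x0_um, y0_um, z0_um = 0, focal_depth_um = 0,
                           microsteps = NULL) {
  structure(list(x0_um = x0_um, y0_um = y0_um, z0_um = z0_um,
                 focal_depth_um = focal_depth_um, microsteps = microsteps),
            class = "tile_placement")
}

# ground-truth depth intensity I(z) for one tile: reflectivity * confocal *
# double-pass attenuation, sampled on the reconstruction depth bins
tile_ground_truth <- function(phantom, placement, tile, laser) {
  n_lat <- tile$n_lat
  pitch <- tile$fov_mm * 1000 / n_lat
  dz <- depth_bin_um(laser)
  zax <- depth_axis_um(laser)
  xs <- placement$x0_um + (seq_len(n_lat) - 0.5) * pitch
  ys <- placement$y0_um + (seq_len(n_lat) - 0.5) * pitch
  gx <- rep(xs, times = n_lat)
  gy <- rep(ys, each = n_lat)
  nzb <- length(zax)
  refl <- mu <- array(0, c(nzb, n_lat, n_lat))
  for (m in seq_len(nzb)) {
    zq <- placement$z0_um + zax[m]
    refl[m, , ] <- interp3(phantom$reflectivity, gx, gy, rep(zq, length(gx)),
                           phantom$voxel_size_um)
    mu[m, , ] <- interp3(phantom$attenuation, gx, gy, rep(zq, length(gx)),
                         phantom$voxel_size_um)
  }
  tz <- confocal_factor(placement$z0_um + zax, placement$focal_depth_um,
                        tile$z_rayleigh_um)
  atten <- apply(mu, c(2, 3), function(v) exp(-2 * cumsum(v) * dz * 1e-3))
  intensity <- refl * tz * atten
  list(intensity = intensity, pitch_um = pitch, dz_um = dz)
}

#' Simulate raw swept-source interference fringes for one tile
#'
#' Forward model inverted by [reconstruct_tile()]: for every lateral sample,
#' the ground-truth depth intensity
#' `I(z) = reflectivity * T(z) * exp(-2 integral mu dz)` is evaluated on the
#' reconstruction depth bins, and a real fringe is synthesized as a sum of
#' cosines at the conjugate bin frequencies with amplitude `sqrt(I)`, so the
#' magnitude-IFFT of the fringe reproduces `sqrt(I)` at the matching depths.
#'
#' Each A-line carries a global phase drawn from a deterministic golden-angle
#' sequence over the lateral raster (`phase_mode = "golden"`). This models the
#' reference-phase diversity between A-lines: it leaves every reconstructed
#' magnitude untouched, while making the tile-average reference fringe
#' negligible, as in real acquisitions where the tile mean isolates the
#' common-mode reference signal. `"zero"` gives fully coherent fringes and
#' `"speckle"` draws independent per-bin phases (a crude speckle switch).
#'
#' @param phantom A [make_phantom()] object.
#' @param placement A [tile_placement()] intersecting the phantom.
#' @param tile A [tile_spec()].
#' @param laser A [laser_spec()].
#' @param noise_sd Gaussian noise sd as a fraction of the maximum fringe
#'   amplitude (>= 0).
#' @param seed Integer seed for the noise (and speckle phases).
#' @param phase_mode One of `"golden"`, `"zero"`, `"speckle"`.
#' @param quantize_12bit Apply 12-bit quantization as done by the digitizer
#'   (off by default).
#' @param keep_truth Attach the ground-truth intensity volume (simulation
#'   convenience for round-trip checks).
#' @return An object of class `fringe_tile` with elements `fringes`
#'   (k-sample x fast-axis x slow-axis), `k_grid`, `placement`, `laser`,
#'   `tile`, and optionally `truth`.
#' @export
simulate_tile_fringes <- function(phantom, placement, tile = tile_spec(),
                                  laser = laser_spec(), noise_sd = 0,
                                  seed = 1L, phase_mode = c("golden", "zero", "speckle"),
                                  quantize_12bit = FALSE, keep_truth = TRUE) {
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  phase_mode <- match.arg(phase_mode)
  fov_um <- tile$fov_mm * 1000
  ext <- phantom$shape * phantom$voxel_size_um
  stop_if(placement$x0_um >= ext[1] || placement$x0_um + fov_um <= 0 ||
            placement$y0_um >= ext[2] || placement$y0_um + fov_um <= 0,
          "tile placement footprint does not intersect the phantom")

  gt <- tile_ground_truth(phantom, placement, tile, laser)
  n <- laser$n_k_samples
  nzb <- n %/% 2L
  n_lat <- tile$n_lat
  amp <- sqrt(pmax(gt$intensity, 0))
  amat <- matrix(amp, nrow = nzb)             # depth bins x lateral samples
  L <- ncol(amat)

  with_seed(seed, {
    phase <- switch(phase_mode,
      zero = matrix(0, nzb, L),
      golden = matrix(rep(2 * pi * ((seq_len(L) - 1) * 0.6180339887498949) %% (2 * pi),
                          each = nzb), nzb, L),
      speckle = matrix(stats::runif(nzb * L, 0, 2 * pi), nzb, L))
    spec <- matrix(0 + 0i, n, L)
    # the (-1)^l factor references the depth phase to the centre of the
    # spectral window (a half-sample shift of the k origin); without it the
    # apodization's transform alternates sign across depth bins and coherent
    # neighbouring bins cancel instead of blurring
    spec[seq_len(nzb), ] <- amat * exp(1i * phase) *
      rep((-1)^(seq_len(nzb) - 1L), ncol(amat))
    fr <- Re(stats::mvfft(spec))              # sum of cosines per A-line
    if (noise_sd > 0) {
      s <- noise_sd * max(abs(fr), 1e-300)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = s), nrow(fr))
    }
    if (quantize_12bit) {
      full <- max(abs(fr))
      if (full > 0) fr <- round(fr / full * 2047) / 2047 * full
    }
    fringes <- array(fr, c(n, n_lat, n_lat))
    structure(list(fringes = fringes, k_grid = k_grid(laser),
                   placement = placement, laser = laser, tile = tile,
                   pitch_um = gt$pitch_um,
                   truth = if (keep_truth) gt$intensity else NULL),
              class = "fringe_tile")
  })
}

#' Simulate a dynamic-focus (OCM) stack of fringe tiles
#'
#' One [simulate_tile_fringes()] volume per focal plane, with focal depth
#' advancing by `tile$ocm_z_step_um` from `z_first_um`. Planes whose focal
#' depth leaves the phantom are dropped with a warning.
#'
#' @param phantom,tile,laser,noise_sd,seed,... As in [simulate_tile_fringes()].
#' @param xy_center_um Lateral centre of the stack (um pair).
#' @param n_planes Number of focal planes (>= 1).
#' @param z_first_um Focal depth of the first plane (um).
#' @return List of `fringe_tile`, ordered by focal depth.
#' @export
simulate_focal_stack <- function(phantom, xy_center_um, n_planes,
                                 tile = tile_spec(), laser = laser_spec(),
                                 z_first_um = 0, noise_sd = 0, seed = 1L, ...) {
  stop_if(n_planes < 1, "n_planes must be >= 1")
  fov_um <- tile$fov_mm * 1000
  depth_ext <- phantom$shape[3] * phantom$voxel_size_um[3]
  zf <- z_first_um + (seq_len(n_planes) - 1L) * tile$ocm_z_step_um
  keep <- zf <= depth_ext
  if (!all(keep)) {
    warning("focal stack exits the phantom; truncated to ", sum(keep), " planes")
    zf <- zf[keep]
  }
  lapply(seq_along(zf), function(i) {
    pl <- tile_placement(xy_center_um[1] - fov_um / 2, xy_center_um[2] - fov_um / 2,
                         z0_um = 0, focal_depth_um = zf[i])
    simulate_tile_fringes(phantom, pl, tile, laser, noise_sd = noise_sd,
                          seed = seed + i - 1L, ...)
  })
}

#' Simulate a multishell diffusion-weighted series from the phantom
#'
#' Monoexponential signal `S_v = S0 * exp(-b_v * D_app) * (1 + drift_v) +
#' noise`, with isotropic fast diffusion in the ventricles (CSF), slower
#' isotropic diffusion in gray matter, and direction-modulated (tensor-like)
#' diffusion along the fiber ribbons; the crossing region mixes both fiber
#' populations. Ventricles have a 3x brighter b0 signal, as fluid does in
#' these long-TE ex vivo scans.
#'
#' @param phantom A [make_phantom()] object.
#' @param scheme A [build_scheme()] gradient table.
#' @param drift Per-volume fractional signal bias (length = number of
#'   volumes, or a single 0).
#' @param noise_sd Gaussian noise sd in signal units (S0 of tissue = 1).
#' @param seed Integer seed.
#' @param voxel_size_um Nominal voxel size stored in the header (um).
#' @return An object of class `dwi_series`: 4-D `signal` (x, y, z, volume),
#'   `scheme`, `voxel_size_um`.
#' @export
simulate_dwi_series <- function(phantom, scheme, drift = 0, noise_sd = 0,
                                seed = 1L, voxel_size_um = 125) {
  nv <- nrow(scheme$table)
  if (length(drift) == 1L && drift[1] == 0) drift <- rep(0, nv)
  stop_if(length(drift) != nv,
          "`drift` length must equal the number of volumes in the scheme")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")

  d_csf <- 2.0e-3   # mm^2/s, free fluid at room temperature
  d_gray <- 0.4e-3  # isotropic ex vivo gray matter
  d_par <- 1.0e-3; d_perp <- 0.15e-3  # fiber tensor eigenvalues

  shape <- phantom$shape
  vent <- phantom$ventricle_mask
  fib1 <- phantom$fiber_mask & !phantom$crossing_mask &
    phantom$atlas_labels == phantom$fiber_tract_labels[1]
  fib2 <- phantom$fiber_mask & !phantom$crossing_mask & !fib1
  crossing <- phantom$crossing_mask
  gray <- phantom$tissue_mask & !phantom$fiber_mask & !vent
  agarose <- phantom$agarose_mask

  s0 <- array(0, shape)
  s0[gray] <- 1; s0[phantom$fiber_mask] <- 1; s0[vent] <- 3; s0[agarose] <- 0.8

  u1 <- c(1, 0, 0); u2 <- c(0, 1, 0)   # ribbon axes (along x / along y)
  tab <- scheme$table
  sig <- array(0, c(shape, nv))
  with_seed(seed, {
    for (v in seq_len(nv)) {
      b <- tab$bval[v]
      g <- c(tab$gx[v], tab$gy[v], tab$gz[v])
      e <- array(0, shape)
      e[gray] <- exp(-b * d_gray)
      e[vent] <- exp(-b * d_csf)
      e[agarose] <- exp(-b * d_csf)
      if (b > 0) {
        dapp <- function(u) d_perp + (d_par - d_perp) * sum(g * u)^2
        e[fib1] <- exp(-b * dapp(u1))
        e[fib2] <- exp(-b * dapp(u2))
        e[crossing] <- 0.5 * (exp(-b * dapp(u1)) + exp(-b * dapp(u2)))
      } else {
        e[phantom$fiber_mask] <- 1
      }
      vol <- s0 * e * (1 + drift[v])
      if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(shape), sd = noise_sd), shape)
      sig[, , , v] <- vol
    }
    structure(list(signal = sig, scheme = scheme,
                   voxel_size_um = rep(voxel_size_um, 3L), seed = seed),
              class = "dwi_series")
  })
}

#' Synthetic dMRI metric maps for the phantom
#'
#' Stand-ins for fitted diffusion metrics with the qualitative structure the
#' real maps have: FA, AFD_max and IC_VF elevated inside fiber bundles, NuFO
#' elevated in the crossing region, OD low in coherent fibers and high in
#' gray matter (so OD and FA rank-correlate negatively over tissue). All
#' bounded maps live in [0, 1].
#'
#' @param phantom A [make_phantom()] object.
#' @param seed Integer seed for the smooth perturbation field.
#' @return An object of class `metric_maps`: list of arrays `FA`, `NuFO`,
#'   `AFD_max`, `OD`, `IC_VF` plus `voxel_size_um`.
#' @export
make_metric_maps <- function(phantom, seed = 1L) {
  shape <- phantom$shape
  fiber <- phantom$fiber_mask
  crossing <- phantom$crossing_mask
  gray <- phantom$tissue_mask & !fiber & !phantom$ventricle_mask
  vent <- phantom$ventricle_mask
  with_seed(seed, {
    pert <- gauss_smooth(array(stats::rnorm(prod(shape)), shape), 2)
    pert <- pert / max(stats::sd(pert), 1e-12)
    mk <- function(g, f, x, v, amp = 0.03) {
      m <- array(0, shape)
      m[gray] <- g; m[fiber] <- f; m[crossing] <- x; m[vent] <- v
      m[phantom$tissue_mask] <- m[phantom$tissue_mask] +
        amp * pert[phantom$tissue_mask]
      m
    }
    fa <- pmin(pmax(mk(0.18, 0.62, 0.45, 0.05), 0), 1)
    nufo <- mk(1, 1, 2, 0, amp = 0)
    afd <- pmax(mk(0.15, 0.55, 0.45, 0.05), 0)
    # dispersion anti-correlates with anisotropy, voxel by voxel
    od <- pmin(pmax(mk(0.65, 0.20, 0.38, 0.9, amp = -0.03), 0), 1)
    icvf <- pmin(pmax(mk(0.35, 0.70, 0.60, 0.02), 0), 1)
    structure(list(FA = fa, NuFO = nufo, AFD_max = afd, OD = od, IC_VF = icvf,
                   voxel_size_um = phantom$voxel_size_um, seed = seed),
              class = "metric_maps")
  })
}
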