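# File-format plumbing: NIfTI-1 volumes, FSL-style gradient tables, fringe
# containers with JSON sidecars, CSV/JSON tables, plain-text transforms and
# the ROI QC figure.

#' Write a volume to NIfTI-1 with um voxel sizes in the header
#'
#' Accepts plain arrays, [intensity_volume()], `brain_volume` or `phantom`
#' fields; voxel sizes are stored in mm as the format requires.
#'
#' @param x Array or a package volume object.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_um Voxel size (um), recycled; ignored when `x` carries
#'   its own.
#' @export
write_volume_nifti <- function(x, path, voxel_size_um = 25) {
  if (inherits(x, "intensity_volume")) {
    voxel_size_um <- x$voxel_size_um; x <- x$intensity
  } else if (inherits(x, "brain_volume")) {
    voxel_size_um <- x$voxel_size_um; x <- x$intensity
  } else if (inherits(x, "overlay_volume")) {
    voxel_size_um <- x$geometry$spacing_um; x <- x$labels
  }
  vs <- rep_len(voxel_size_um, 3) / 1000
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume; returns the array with `voxel_size_um` attribute
#' @param path NIfTI file path.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "voxel_size_um") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(a))))] * 1000
  a
}

#' Write a phantom's fields as a directory of NIfTI volumes
#' @param phantom A [make_phantom()].
#' @param dir Output directory (created).
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fields <- c("reflectivity", "attenuation", "tissue_mask", "fiber_mask",
              "vessel_mask", "ventricle_mask", "atlas_labels")
  for (f in fields)
    write_volume_nifti(phantom[[f]] * 1, file.path(dir, paste0(f, ".nii.gz")),
                       phantom$voxel_size_um)
  invisible(dir)
}

#' Write a DWI series as 4-D NIfTI plus FSL-style bval/bvec tables
#' @param dwi A DWI series.
#' @param prefix Output path prefix (writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`).
#' @export
write_dwi_fsl <- function(dwi, prefix) {
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(rep_len(dwi$voxel_size_um, 3) / 1000, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  tab <- dwi$scheme$table
  writeLines(paste(tab$bval, collapse = " "), paste0(prefix, ".bval"))
  writeLines(c(paste(tab$gx, collapse = " "), paste(tab$gy, collapse = " "),
               paste(tab$gz, collapse = " ")), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read an FSL-style bval/bvec pair into a gradient scheme
#' @param bval_path,bvec_path Text files (1 x n and 3 x n).
#' @export
read_scheme_fsl <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  g <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  stop_if(ncol(g) != length(b), "bval/bvec lengths differ")
  shells <- sort(unique(b[b > 0]))
  tab <- data.frame(index = seq_along(b), bval = b,
                    gx = g[1, ], gy = g[2, ], gz = g[3, ],
                    shell = match(b, shells, nomatch = 0L))
  structure(list(table = tab, b_values = shells, n_b0 = sum(b == 0)),
            class = "gradient_scheme")
}

#' Save a fringe tile as a binary container with a JSON sidecar
#'
#' Float32 fringes in column order plus a sidecar recording the array shape,
#' the k-grid, the placement and the laser specification.
#' @param tile A `fringe_tile`.
#' @param prefix Path prefix (writes `<prefix>.fringe` and `<prefix>.json`).
#' @export
write_fringe_tile <- function(tile, prefix) {
  con <- file(paste0(prefix, ".fringe"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(tile$fringes), con, size = 4)
  side <- list(shape = dim(tile$fringes), k_grid = tile$k_grid,
               placement = tile$placement[c("x0_um", "y0_um", "z0_um",
                                            "focal_depth_um")],
               laser = unclass(tile$laser), pitch_um = tile$pitch_um)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Load a fringe tile saved by [write_fringe_tile()]
#' @param prefix Path prefix.
#' @export
read_fringe_tile <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(side$shape)
  con <- file(paste0(prefix, ".fringe"), "rb")
  on.exit(close(con))
  fr <- readBin(con, numeric(), n = n, size = 4)
  laser <- do.call(laser_spec, as.list(side$laser[c("lambda0_nm",
    "tuning_bandwidth_nm", "n_k_samples", "apod_mu_nm", "apod_sigma_nm",
    "n_medium")]))
  structure(list(fringes = array(fr, side$shape), k_grid = side$k_grid,
                 placement = do.call(tile_placement, as.list(side$placement)),
                 laser = laser, tile = NULL, pitch_um = side$pitch_um),
            class = "fringe_tile")
}

#' Write / read ROI tables as CSV
#' @param rois A `roi_spec` data frame.
#' @param path CSV path.
#' @export
write_rois_csv <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("roi_spec", "data.frame")
  out
}

#' Export an attenuation fit: per-A-line CSV plus a JSON summary
#' @param fit An [fit_attenuation()] result.
#' @param prefix Path prefix (`<prefix>.csv`, `<prefix>.json`).
#' @export
write_attenuation_fit <- function(fit, prefix) {
  d <- dim(fit$mu)
  df <- data.frame(ix = rep(seq_len(d[1]), d[2]),
                   iy = rep(seq_len(d[2]), each = d[1]),
                   mu_mm1 = as.vector(fit$mu), i0 = as.vector(fit$i0),
                   residual = as.vector(fit$residual))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(mu_median_mm1 = fit$mu_median, z_f_um = fit$z_f_um,
                            z_r_um = fit$z_r_um,
                            surface_z_um = fit$surface_z_um,
                            n_valid = sum(is.finite(fit$mu))),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a drift profile as CSV
#' @param drift A [estimate_drift()] profile.
#' @param path CSV path.
#' @export
write_drift_csv <- function(drift, path) {
  utils::write.csv(data.frame(volume = seq_along(drift$drift),
                              shell = drift$shell, measured = drift$measured,
                              synthetic = drift$synthetic, raw = drift$raw,
                              drift = drift$drift),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a 4x4 plain-text affine matrix
#' @param path Whitespace-delimited 4x4 matrix file.
#' @export
read_affine_txt <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  affine_transform(m)
}

#' QC figure of the automated ROI selection
#'
#' Four panels in the acquisition's style: the slice AIP, the tissue mask
#' with the margin contour, the probability bias map, and the AIP with the
#' accepted ROI boxes.
#'
#' @param aip Slice AIP matrix.
#' @param mask A [segment_tissue()] mask.
#' @param pmap A [probability_map()].
#' @param rois A `roi_spec` table.
#' @param path Output PNG path.
#' @param margin_um Margin used for the contour.
#' @export
qc_roi_figure <- function(aip, mask, pmap, rois, path, margin_um = 250) {
  px <- pmap$pixel_size_um
  grDevices::png(path, width = 1200, height = 1200)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  show <- function(m, main) graphics::image(seq_len(nrow(m)) * px,
                                            seq_len(ncol(m)) * px, m,
                                            col = grDevices::gray.colors(256),
                                            asp = 1, main = main,
                                            xlab = "", ylab = "")
  show(aip, "slice AIP")
  mm <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  show(mm * 1, "tissue mask + margin")
  inner <- roi_candidates(mask, margin_um, px)
  graphics::contour(seq_len(nrow(inner)) * px, seq_len(ncol(inner)) * px,
                    inner * 1, levels = 0.5, add = TRUE, col = "red",
                    drawlabels = FALSE)
  show(pmap$p, "probability bias")
  show(aip, "selected ROIs")
  if (nrow(rois)) {
    half <- rois$fov_mm * 1000 / 2
    graphics::rect(rois$x_um - half, rois$y_um - half,
                   rois$x_um + half, rois$y_um + half,
                   border = "red", lwd = 2)
  }
  invisible(path)
}
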