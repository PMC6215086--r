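# Locating high-resolution ROIs in the assembled brain, labeled overlay
# volumes, and carrying them through given affine transforms.
#
# Volumes handled here are (x, y, z) arrays on grids described by
# `grid_geometry()`; transforms are 4x4 homogeneous matrices in physical um
# coordinates (plain-text ITK-style matrices are accepted by the readers).

#' Grid geometry descriptor
#'
#' @param origin_um Physical position of the grid corner (x, y, z), um.
#' @param spacing_um Voxel size per axis (um), recycled to length 3.
#' @param dim Voxel counts (nx, ny, nz).
#' @export
grid_geometry <- function(origin_um = c(0, 0, 0), spacing_um = 25, dim) {
  structure(list(origin_um = origin_um, spacing_um = rep_len(spacing_um, 3),
                 dim = as.integer(dim)), class = "grid_geometry")
}

#' Zero-mean normalized cross-correlation template matching
#'
#' Finds the offset of a small template inside a larger image by maximizing
#' the zero-mean normalized cross-correlation (computed for every valid
#' placement via FFT cross-correlation plus summed-area tables, so it equals
#' the brute-force correlation loop exactly up to round-off). The search can
#' be restricted to a window around an expected position — the stage has a
#' known repeatability, so +-1 mm is the working default at the 25 um/px
#' mosaic resolution.
#'
#' @param image Matrix (slice AIP).
#' @param template Matrix, strictly smaller than `image`, non-constant.
#' @param expected_px Optional expected top-left position (row, col, 1-based).
#' @param window_px Half-width of the search window around `expected_px`
#'   (pixels); ignored when `expected_px` is NULL.
#' @param pixel_size_um Pixel size, used only to report the offset in um.
#' @return List: `pos_px` (top-left, 1-based), `offset_um`, `score`
#'   (in [-1, 1]), `ncc` (the masked score map).
#' @export
match_template <- function(image, template, expected_px = NULL,
                           window_px = 40L, pixel_size_um = 25) {
  di <- dim(image); dt <- dim(template)
  stop_if(any(dt > di), "template must be smaller than the image")
  stop_if(stats::sd(template) == 0, "degenerate input: constant template")
  t0 <- template - mean(template)
  st <- sqrt(sum(t0^2))
  stop_if(st == 0, "degenerate input: constant template")

  # FFT cross-correlation of the image with the zero-mean template
  pr <- di[1]; pc <- di[2]
  TI <- matrix(0, pr, pc)
  TI[seq_len(dt[1]), seq_len(dt[2])] <- t0
  num_full <- Re(stats::fft(stats::fft(image) * Conj(stats::fft(TI)), inverse = TRUE)) / (pr * pc)
  nr <- di[1] - dt[1] + 1L; nc <- di[2] - dt[2] + 1L
  num <- num_full[seq_len(nr), seq_len(nc)]

  # local sums over template-sized patches via summed-area tables
  sat <- function(m) {
    s <- apply(apply(m, 2, cumsum), 1, cumsum)
    rbind(0, cbind(0, t(s)))
  }
  boxsum <- function(S) {
    S[(dt[1] + 1):(di[1] + 1), (dt[2] + 1):(di[2] + 1)] -
      S[1:nr, (dt[2] + 1):(di[2] + 1)] -
      S[(dt[1] + 1):(di[1] + 1), 1:nc] + S[1:nr, 1:nc]
  }
  s1 <- boxsum(sat(image))
  s2 <- boxsum(sat(image^2))
  npx <- prod(dt)
  varp <- pmax(s2 - s1^2 / npx, 0)
  ncc <- matrix(0, nr, nc)
  ok <- varp > (1e-12 * max(varp, .Machine$double.eps))
  ncc[ok] <- num[ok] / (sqrt(varp[ok]) * st)
  ncc <- pmin(pmax(ncc, -1), 1)

  if (!is.null(expected_px)) {
    ri <- seq_len(nr); ci <- seq_len(nc)
    maskr <- abs(ri - expected_px[1]) > window_px
    maskc <- abs(ci - expected_px[2]) > window_px
    ncc[maskr, ] <- -Inf
    ncc[, maskc] <- -Inf
  }
  pk <- arrayInd(which.max(ncc), dim(ncc))
  list(pos_px = as.integer(pk),
       offset_um = (as.numeric(pk) - 1) * pixel_size_um,
       score = ncc[pk], ncc = ncc)
}

#' Rasterize ROI specifications into a labeled overlay volume
#'
#' Each ROI becomes an axis-aligned block of its field of view centred at its
#' registered (x, y) position, spanning axially from its slice position plus
#' first focal plane over its OCM thickness. Later ROIs overwrite earlier
#' ones where blocks collide (logged as a warning); 0 is background.
#'
#' @param rois A `roi_spec` data frame ([sample_rois()] format). Absolute z
#'   is `slice_z_um[slice_index + 1] + z0_um` when `slice_z_um` is given,
#'   else `slice_index * slice_thickness_um + z0_um`.
#' @param geometry A [grid_geometry()] matching the assembled brain.
#' @param slice_z_um Optional per-slice z positions (um).
#' @param slice_thickness_um Slice advance (um) when `slice_z_um` is absent.
#' @return An object of class `overlay_volume`: `labels` (integer array
#'   (nx, ny, nz)), `geometry`, `roi_table`.
#' @export
build_overlay <- function(rois, geometry, slice_z_um = NULL,
                          slice_thickness_um = 200) {
  dm <- geometry$dim; sp <- geometry$spacing_um; o <- geometry$origin_um
  lab <- array(0L, dm)
  if (nrow(rois)) {
    xc <- o[1] + (seq_len(dm[1]) - 0.5) * sp[1]
    yc <- o[2] + (seq_len(dm[2]) - 0.5) * sp[2]
    zc <- o[3] + (seq_len(dm[3]) - 0.5) * sp[3]
    collided <- FALSE
    for (r in seq_len(nrow(rois))) {
      half <- rois$fov_mm[r] * 1000 / 2
      zt <- if (!is.null(slice_z_um)) slice_z_um[rois$slice_index[r] + 1L]
            else rois$slice_index[r] * slice_thickness_um
      zt <- zt + rois$z0_um[r]
      ix <- which(xc >= rois$x_um[r] - half & xc < rois$x_um[r] + half)
      iy <- which(yc >= rois$y_um[r] - half & yc < rois$y_um[r] + half)
      iz <- which(zc >= zt & zc < zt + rois$thickness_um[r])
      if (!length(ix) || !length(iy) || !length(iz)) next
      if (any(lab[ix, iy, iz] != 0L)) collided <- TRUE
      lab[ix, iy, iz] <- rois$label[r]
    }
    if (collided) warning("ROI blocks collide; later labels overwrite earlier")
  }
  structure(list(labels = lab, geometry = geometry, roi_table = rois),
            class = "overlay_volume")
}

#' 4x4 affine transform in physical coordinates
#'
#' @param matrix 4x4 homogeneous matrix (um frame), invertible.
#' @param direction `"forward"` maps source to target coordinates.
#' @export
affine_transform <- function(matrix, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  m <- rbind(matrix)
  stop_if(!all(dim(m) == c(4, 4)), "need a 4x4 matrix")
  dt <- det(m)
  stop_if(!is.finite(dt) || abs(dt) < 1e-12, "singular transform")
  if (direction == "inverse") m <- solve(m)
  structure(list(matrix = m), class = "affine_transform")
}

#' Apply a sequence of affine transforms to a labeled overlay
#'
#' Composes the transforms in application order (first listed is applied
#' first) and resamples the labels into the target grid by nearest-neighbour
#' pull-back through the composed inverse, so no labels are invented.
#'
#' @param overlay An [build_overlay()] volume.
#' @param transforms A single [affine_transform()] (or 4x4 matrix) or a list
#'   of them, applied sequentially.
#' @param target_geometry A [grid_geometry()] for the output.
#' @return A transformed `overlay_volume` on the target grid.
#' @export
apply_affine <- function(overlay, transforms, target_geometry) {
  if (inherits(transforms, "affine_transform") || is.matrix(transforms))
    transforms <- list(transforms)
  transforms <- lapply(transforms, function(t)
    if (inherits(t, "affine_transform")) t else affine_transform(t))
  comp <- Reduce(function(acc, t) t$matrix %*% acc, transforms, init = diag(4))
  inv <- solve(comp)

  dm <- target_geometry$dim; sp <- target_geometry$spacing_um
  o <- target_geometry$origin_um
  xc <- o[1] + (seq_len(dm[1]) - 0.5) * sp[1]
  yc <- o[2] + (seq_len(dm[2]) - 0.5) * sp[2]
  zc <- o[3] + (seq_len(dm[3]) - 0.5) * sp[3]
  P <- cbind(rep(xc, times = dm[2] * dm[3]),
             rep(rep(yc, each = dm[1]), times = dm[3]),
             rep(zc, each = dm[1] * dm[2]), 1)
  S <- P %*% t(inv)
  sg <- overlay$geometry
  i <- round((S[, 1] - sg$origin_um[1]) / sg$spacing_um[1] + 0.5)
  j <- round((S[, 2] - sg$origin_um[2]) / sg$spacing_um[2] + 0.5)
  k <- round((S[, 3] - sg$origin_um[3]) / sg$spacing_um[3] + 0.5)
  sd_ <- sg$dim
  ok <- i >= 1 & i <= sd_[1] & j >= 1 & j <= sd_[2] & k >= 1 & k <= sd_[3]
  lab <- integer(nrow(P))
  lab[ok] <- overlay$labels[cbind(i[ok], j[ok], k[ok])]
  structure(list(labels = array(lab, dm), geometry = target_geometry,
                 roi_table = overlay$roi_table),
            class = "overlay_volume")
}

#' Atlas structure volume fractions per ROI
#'
#' Histograms the atlas labels under every ROI block and normalizes to
#' fractions; an ROI is flagged as a fiber-tract ROI when any overlapping
#' atlas structure belongs to `fiber_labels`.
#'
#' @param overlay An `overlay_volume` on the atlas grid.
#' @param atlas Integer label array of the same dimensions.
#' @param fiber_labels Atlas labels in the "fiber tracts" ontology subset.
#' @return An object of class `structure_fractions`: `fractions` (data frame
#'   roi / structure / fraction), `fiber_flag` (named logical per ROI).
#' @export
structure_fractions <- function(overlay, atlas, fiber_labels = integer(0)) {
  stop_if(!all(dim(overlay$labels) == dim(atlas)), "grid mismatch")
  rlab <- sort(unique(as.integer(overlay$labels[overlay$labels > 0])))
  rows <- list(); flag <- logical(length(rlab)); names(flag) <- rlab
  for (r in seq_along(rlab)) {
    sel <- atlas[overlay$labels == rlab[r]]
    tb <- table(sel)
    fr <- as.numeric(tb) / length(sel)
    rows[[r]] <- data.frame(roi = rlab[r],
                            structure = as.integer(names(tb)),
                            fraction = fr)
    flag[r] <- any(as.integer(names(tb)) %in% fiber_labels)
  }
  structure(list(fractions = do.call(rbind, rows) %||%
                   data.frame(roi = integer(0), structure = integer(0),
                              fraction = numeric(0)),
                 fiber_flag = flag),
            class = "structure_fractions")
}

#' Mean metric value under each ROI block
#'
#' NaN-aware mean of a metric map over every labeled block of the overlay
#' (both on the same grid, i.e. after [apply_affine()] into metric space).
#'
#' @param overlay An `overlay_volume`.
#' @param metric Numeric array of the same dimensions.
#' @return Named numeric vector of per-ROI means (NA when a block has no
#'   voxels with data).
#' @export
roi_metric_average <- function(overlay, metric) {
  stop_if(!all(dim(overlay$labels) == dim(metric)), "grid mismatch")
  rlab <- sort(unique(as.integer(overlay$labels[overlay$labels > 0])))
  out <- vapply(rlab, function(l) {
    v <- metric[overlay$labels == l]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  stats::setNames(out, rlab)
}
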