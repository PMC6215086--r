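# Stage-coordinate model, tile stitching with feathered (diffusion-style)
# blending, and 3-D whole-brain assembly.
#
# Resampling convention: linear interpolation, pixel centers at half-integer
# physical coordinates ((i - 0.5) * spacing from the grid origin), 0-based
# physical frames, half-open tile extents [x0, x0 + fov).

#' Integer (optionally subpixel) shift between two images by phase correlation
#'
#' Returns the translation `s` maximizing the inverse transform of the
#' normalized cross-power spectrum, such that `img_b` is `img_a` circularly
#' shifted by `s` (rows, cols). Wrap-around shifts are mapped to the signed
#' range `(-n/2, n/2]`.
#'
#' @param img_a,img_b Equal-shaped, non-constant matrices.
#' @param subpixel Apply 3-point parabolic refinement per axis.
#' @return List with `shift` (length-2, rows/cols), `score` (peak of the
#'   correlation surface).
#' @export
phase_correlation <- function(img_a, img_b, subpixel = FALSE) {
  stop_if(!all(dim(img_a) == dim(img_b)), "images must have equal shapes")
  stop_if(stats::sd(img_a) == 0 || stats::sd(img_b) == 0,
          "degenerate input: constant image")
  fa <- stats::fft(img_a)
  fb <- stats::fft(img_b)
  r <- fb * Conj(fa)
  r <- r / pmax(Mod(r), .Machine$double.eps)
  surf <- Re(stats::fft(r, inverse = TRUE)) / length(r)
  pk <- arrayInd(which.max(surf), dim(surf))
  n <- dim(surf)
  shift <- as.numeric(pk - 1L)
  shift <- ifelse(shift > n / 2, shift - n, shift)
  if (subpixel) {
    for (ax in 1:2) {
      idx <- pk
      vm <- vp <- idx
      vm[ax] <- (idx[ax] - 2L) %% n[ax] + 1L
      vp[ax] <- idx[ax] %% n[ax] + 1L
      y1 <- surf[vm]; y2 <- surf[idx]; y3 <- surf[vp]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > .Machine$double.eps)
        shift[ax] <- shift[ax] - 0.5 * (y3 - y1) / den
    }
  }
  list(shift = shift, score = max(surf))
}

#' Calibrate the stage transform p = A pM + b
#'
#' Least-squares fit of the affine model mapping stage microsteps to Cartesian
#' positions, from commanded displacements and the translations measured
#' between the images recorded at each location (phase correlation in
#' practice).
#'
#' @param commanded_microsteps n x 2 matrix of microstep positions.
#' @param measured_um n x 2 matrix of measured Cartesian positions (um).
#' @return An object of class `stage_model`: `A` (2 x 2), `b` (length 2),
#'   `residual_rms_um`.
#' @export
calibrate_stage <- function(commanded_microsteps, measured_um) {
  pm <- as.matrix(commanded_microsteps)
  p <- as.matrix(measured_um)
  stop_if(nrow(pm) < 3, "need >= 3 displacement pairs")
  stop_if(!all(dim(pm) == dim(p)), "input dimensions differ")
  X <- cbind(pm, 1)
  qx <- qr(X)
  stop_if(qx$rank < 3, "rank deficiency: collinear microstep positions")
  coef <- qr.coef(qx, p)
  fitted <- X %*% coef
  rms <- sqrt(mean((p - fitted)^2))
  structure(list(A = unname(t(coef[1:2, , drop = FALSE])),
                 b = unname(as.numeric(coef[3, ])),
                 residual_rms_um = rms),
            class = "stage_model")
}

#' Identity stage model (microsteps already in um)
#' @export
stage_model_identity <- function() {
  structure(list(A = diag(2), b = c(0, 0), residual_rms_um = 0),
            class = "stage_model")
}

#' Convert stage microsteps to Cartesian positions (um)
#'
#' @param model A [calibrate_stage()] model.
#' @param pm Microstep pair, or an n x 2 matrix of pairs.
#' @export
microsteps_to_cartesian <- function(model, pm) {
  pm <- rbind(pm)
  out <- t(model$A %*% t(pm) + model$b)
  unname(out[seq_len(nrow(pm)), , drop = (nrow(pm) == 1)])
}

#' Invert a stage model: Cartesian positions back to microsteps
#' @param model A `stage_model`.
#' @param p Cartesian um pair or n x 2 matrix.
#' @export
cartesian_to_microsteps <- function(model, p) {
  p <- rbind(p)
  out <- t(solve(model$A) %*% (t(p) - model$b))
  unname(out[seq_len(nrow(p)), , drop = (nrow(p) == 1)])
}

#' Feathered blending weights over a pixel grid
#'
#' Diffusion-style blending implemented as normalized distance-to-boundary
#' feathering: each tile's raw weight is its interior distance to the closest
#' tile edge (the steady state of a diffusion construction on the footprint),
#' and weights are normalized so all tiles covering a pixel sum to exactly 1.
#' A tile alone on a pixel always receives weight 1. An iterative heat-kernel
#' variant (`method = "heat"`) smooths each footprint indicator with a
#' Gaussian before normalization and exists to cross-validate the default.
#'
#' @param footprints n x 4 matrix (x0, x1, y0, y1) of tile extents (um),
#'   half-open.
#' @param grid List with `origin_um` (x, y), `spacing_um`, `dim` (nx, ny).
#' @param method `"distance"` (default) or `"heat"`.
#' @param heat_sigma_um Gaussian sigma of the heat-kernel variant.
#' @return List of weight matrices (nx x ny), one per tile; attribute
#'   `coverage` is the number of tiles covering each pixel.
#' @export
blend_weights <- function(footprints, grid, method = c("distance", "heat"),
                          heat_sigma_um = NULL) {
  method <- match.arg(method)
  fp <- rbind(footprints)
  nx <- grid$dim[1]; ny <- grid$dim[2]; sp <- grid$spacing_um
  xc <- grid$origin_um[1] + (seq_len(nx) - 0.5) * sp
  yc <- grid$origin_um[2] + (seq_len(ny) - 0.5) * sp
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  eps <- 1e-9 * sp
  raw <- vector("list", nrow(fp))
  for (t in seq_len(nrow(fp))) {
    inside <- X >= fp[t, 1] & X < fp[t, 2] & Y >= fp[t, 3] & Y < fp[t, 4]
    if (method == "distance") {
      d <- pmin(pmin(X - fp[t, 1], fp[t, 2] - X), pmin(Y - fp[t, 3], fp[t, 4] - Y))
      w <- ifelse(inside, pmax(d, eps), 0)
    } else {
      sig <- (heat_sigma_um %||% ((fp[t, 2] - fp[t, 1]) * 0.1)) / sp
      w <- gauss_smooth(ifelse(inside, 1, 0), sig) * inside
      w <- pmax(w, eps * inside)
    }
    raw[[t]] <- w
  }
  tot <- Reduce(`+`, raw)
  cover <- Reduce(`+`, lapply(raw, function(w) (w > 0) * 1L))
  out <- lapply(raw, function(w) ifelse(tot > 0, w / pmax(tot, eps), 0))
  attr(out, "coverage") <- cover
  out
}

#' Stitch reconstructed tiles into a slice mosaic
#'
#' Tiles are placed at their recorded Cartesian positions (no pairwise
#' registration), resampled onto the slice raster by linear interpolation,
#' and blended with [blend_weights()]. Produces the 3-D slice volume and its
#' 2-D average intensity projection (mean over the first `aip_depth_um` of
#' depth, which is where the slice's own tissue lives).
#'
#' @param tiles List of [intensity_volume()] sharing voxel size and z axis.
#' @param grid_spacing_um Output pixel size; defaults to the tile pixel size.
#' @param aip_depth_um Depth range aggregated into the AIP (um).
#' @param slice_index Slice number (0-based).
#' @param z_position_um Depth of this slice's top face in the assembled brain.
#' @return An object of class `slice_mosaic`: `volume` (z x nx x ny), `aip`
#'   (nx x ny), `weights`, `grid`, `placements`, `slice_index`,
#'   `z_position_um`, `thickness_um`.
#' @export
stitch_slice <- function(tiles, grid_spacing_um = NULL, aip_depth_um = 800,
                         slice_index = 0L, z_position_um = 0) {
  stop_if(length(tiles) < 1, "need >= 1 tile")
  vs <- tiles[[1]]$voxel_size_um
  for (t in tiles) stop_if(any(abs(t$voxel_size_um - vs) > 1e-9),
                           "tiles must share voxel size")
  sp <- grid_spacing_um %||% vs[2]
  nz <- dim(tiles[[1]]$intensity)[1]
  fov <- vapply(tiles, function(t) dim(t$intensity)[2] * t$voxel_size_um[2], 0)
  x0 <- vapply(tiles, function(t) t$origin_um[1], 0)
  y0 <- vapply(tiles, function(t) t$origin_um[2], 0)
  xmin <- min(x0); ymin <- min(y0)
  xmax <- max(x0 + fov); ymax <- max(y0 + fov)
  nxg <- as.integer(ceiling((xmax - xmin) / sp - 1e-9))
  nyg <- as.integer(ceiling((ymax - ymin) / sp - 1e-9))
  grid <- list(origin_um = c(xmin, ymin), spacing_um = sp, dim = c(nxg, nyg))
  fp <- cbind(x0, x0 + fov, y0, y0 + fov)
  w <- blend_weights(fp, grid)
  cover <- Reduce(`+`, lapply(w, function(m) m > 0))
  if (any(cover == 0)) warning("mosaic has uncovered pixels (disjoint tiles)")

  xc <- grid$origin_um[1] + (seq_len(nxg) - 0.5) * sp
  yc <- grid$origin_um[2] + (seq_len(nyg) - 0.5) * sp
  vol <- array(0, c(nz, nxg, nyg))
  for (t in seq_along(tiles)) {
    wt <- w[[t]]
    idx <- which(wt > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    ri <- (xc[idx[, 1]] - tiles[[t]]$origin_um[1]) / vs[2] + 0.5
    ci <- (yc[idx[, 2]] - tiles[[t]]$origin_um[2]) / vs[3] + 0.5
    for (z in seq_len(nz)) {
      v <- interp2_idx(tiles[[t]]$intensity[z, , ], ri, ci)
      v[is.na(v)] <- 0
      plane <- vol[z, , ]
      plane[idx] <- plane[idx] + wt[idx] * v
      vol[z, , ] <- plane
    }
  }
  nz_aip <- max(1L, min(nz, as.integer(round(aip_depth_um / vs[1]))))
  aip <- apply(vol[seq_len(nz_aip), , , drop = FALSE], c(2, 3), mean)
  structure(list(volume = vol, aip = aip, weights = w, grid = grid,
                 voxel_size_um = c(vs[1], sp, sp),
                 placements = data.frame(tile = seq_along(tiles), x0_um = x0,
                                         y0_um = y0, fov_um = fov),
                 slice_index = slice_index, z_position_um = z_position_um,
                 thickness_um = nz * vs[1]),
            class = "slice_mosaic")
}

#' Assemble stitched slices into a whole-brain volume
#'
#' Resamples every slice onto an isotropic output grid (25 um by default) and
#' blends the ~100 um axial overlaps between consecutive slices with 1-D
#' feathering weights (distance to the slice's own z boundaries) normalized
#' to sum to 1 wherever at least one slice has data.
#'
#' @param slices List of [stitch_slice()] mosaics ordered by `z_position_um`.
#' @param out_voxel_um Output voxel size (um, isotropic).
#' @return An object of class `brain_volume`: `intensity` (z x nx x ny),
#'   `voxel_size_um`, `origin_um` (x, y, z), `slice_table`.
#' @export
assemble_brain <- function(slices, out_voxel_um = 25) {
  stop_if(length(slices) < 1, "need >= 1 slice")
  zpos <- vapply(slices, function(s) s$z_position_um, 0)
  stop_if(is.unsorted(zpos, strictly = length(slices) > 1), "slices must be ordered by z")
  thick <- vapply(slices, function(s) s$thickness_um, 0)
  if (length(slices) > 1 && any(zpos[-1] > (zpos + thick)[-length(zpos)] + 1e-9))
    warning("gap between consecutive slices; assembled with a hole")
  xmin <- min(vapply(slices, function(s) s$grid$origin_um[1], 0))
  ymin <- min(vapply(slices, function(s) s$grid$origin_um[2], 0))
  xmax <- max(vapply(slices, function(s) s$grid$origin_um[1] + s$grid$dim[1] * s$grid$spacing_um, 0))
  ymax <- max(vapply(slices, function(s) s$grid$origin_um[2] + s$grid$dim[2] * s$grid$spacing_um, 0))
  zmin <- min(zpos); zmax <- max(zpos + thick)
  nx <- as.integer(ceiling((xmax - xmin) / out_voxel_um - 1e-9))
  ny <- as.integer(ceiling((ymax - ymin) / out_voxel_um - 1e-9))
  nz <- as.integer(ceiling((zmax - zmin) / out_voxel_um - 1e-9))
  xc <- xmin + (seq_len(nx) - 0.5) * out_voxel_um
  yc <- ymin + (seq_len(ny) - 0.5) * out_voxel_um
  zc <- zmin + (seq_len(nz) - 0.5) * out_voxel_um
  eps <- 1e-9 * out_voxel_um

  acc <- array(0, c(nz, nx, ny))
  wz_all <- matrix(0, nz, length(slices))
  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    inz <- zc >= sl$z_position_um & zc < sl$z_position_um + sl$thickness_um
    d <- pmin(zc - sl$z_position_um, sl$z_position_um + sl$thickness_um - zc)
    wz_all[, s] <- ifelse(inz, pmax(d, eps), 0)
  }
  wtot <- rowSums(wz_all)
  wz_all <- wz_all / pmax(wtot, eps)
  wz_all[wtot == 0, ] <- 0

  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    active <- which(wz_all[, s] > 0)
    if (!length(active)) next
    # lateral resampling of the slice grid onto the output grid
    ri <- (xc - sl$grid$origin_um[1]) / sl$grid$spacing_um + 0.5
    ci <- (yc - sl$grid$origin_um[2]) / sl$grid$spacing_um + 0.5
    RI <- matrix(ri, nx, ny); CI <- matrix(ci, nx, ny, byrow = TRUE)
    nzs <- dim(sl$volume)[1]
    for (z in active) {
      zi <- (zc[z] - sl$z_position_um) / sl$voxel_size_um[1] + 0.5
      zi <- min(max(zi, 1), nzs)
      lo <- floor(zi); hi <- min(lo + 1, nzs); tz <- zi - lo
      plane <- (1 - tz) * sl$volume[lo, , ] + tz * sl$volume[hi, , ]
      v <- interp2_idx(plane, as.vector(RI), as.vector(CI))
      v[is.na(v)] <- 0
      acc[z, , ] <- acc[z, , ] + wz_all[z, s] * matrix(v, nx, ny)
    }
  }
  structure(list(intensity = acc, voxel_size_um = rep(out_voxel_um, 3),
                 origin_um = c(xmin, ymin, zmin),
                 slice_weights = wz_all,
                 slice_table = data.frame(slice = seq_along(slices),
                                          z_um = zpos, thickness_um = thick)),
            class = "brain_volume")
}

#' Cover a closed polygon with a minimal grid of overlapping tiles
#'
#' Axis-aligned grid of square tiles (side `fov_mm`) at stride
#' `fov_mm * (1 - overlap_fraction)` whose union covers the polygon's
#' bounding box; grid size is the ceiling of covered span over stride.
#'
#' @param polygon n x 2 matrix of vertices (um), closed or implicitly closed,
#'   simple (non-self-intersecting).
#' @param tile A [tile_spec()].
#' @return Data frame with tile ids and lower-corner positions (um).
#' @export
polygon_to_tiles <- function(polygon, tile = tile_spec()) {
  p <- as.matrix(polygon)
  stop_if(nrow(p) < 3, "polygon needs >= 3 vertices")
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  stop_if(polygon_self_intersects(p), "invalid argument: self-intersecting polygon")
  fov <- tile$fov_mm * 1000
  stride <- tile$stride_mm * 1000
  x0 <- min(p[, 1]); y0 <- min(p[, 2])
  spanx <- max(p[, 1]) - x0; spany <- max(p[, 2]) - y0
  nx <- max(1L, as.integer(ceiling((spanx - fov) / stride - 1e-9)) + 1L)
  ny <- max(1L, as.integer(ceiling((spany - fov) / stride - 1e-9)) + 1L)
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(tile = seq_len(nrow(g)),
             x0_um = x0 + g$ix * stride, y0_um = y0 + g$iy * stride,
             fov_um = fov)
}

# O(n^2) proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- cross(a, b, c); d2 <- cross(a, b, d)
      d3 <- cross(c, d, a); d4 <- cross(c, d, b)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Raster tile grid covering a rectangular region
#'
#' Convenience for serial acquisitions: tiles at the acquisition stride
#' starting at `(x0, y0)`.
#' @param x0_um,y0_um Lower corner (um).
#' @param n_x,n_y Tiles per axis.
#' @param tile A [tile_spec()].
#' @export
tile_raster <- function(x0_um, y0_um, n_x, n_y, tile = tile_spec()) {
  stride <- tile$stride_mm * 1000
  g <- expand.grid(ix = seq_len(n_x) - 1L, iy = seq_len(n_y) - 1L)
  data.frame(tile = seq_len(nrow(g)),
             x0_um = x0_um + g$ix * stride, y0_um = y0_um + g$iy * stride,
             fov_um = tile$fov_mm * 1000)
}
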