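# Automated high-resolution ROI positioning: tissue segmentation of the slice
# AIP, probability bias map, and margin/separation-constrained weighted
# sampling of ROI centers.

#' Bilateral filter (edge-preserving denoiser)
#'
#' Plain Gaussian-range bilateral filter with a square support window; used to
#' denoise slice AIPs before thresholding.
#'
#' @param img Matrix.
#' @param sigma_spatial_px Spatial Gaussian sigma (pixels).
#' @param sigma_range Range Gaussian sigma; default 0.1 of the dynamic range.
#' @param radius_px Window half-width; default `ceiling(2 * sigma_spatial)`.
#' @export
bilateral_filter <- function(img, sigma_spatial_px = 3, sigma_range = NULL,
                             radius_px = NULL) {
  rng <- diff(range(img))
  sigma_range <- sigma_range %||% (0.1 * max(rng, .Machine$double.eps))
  h <- radius_px %||% ceiling(2 * sigma_spatial_px)
  d <- dim(img)
  pad <- matrix(0, d[1] + 2 * h, d[2] + 2 * h)
  # reflected padding
  ri <- c(rev(seq_len(h) + 1L), seq_len(d[1]), d[1] - seq_len(h))
  ci <- c(rev(seq_len(h) + 1L), seq_len(d[2]), d[2] - seq_len(h))
  pad <- img[pmin(pmax(ri, 1L), d[1]), pmin(pmax(ci, 1L), d[2])]
  num <- den <- matrix(0, d[1], d[2])
  for (dx in -h:h) for (dy in -h:h) {
    ws <- exp(-(dx^2 + dy^2) / (2 * sigma_spatial_px^2))
    if (ws < 1e-4) next
    nb <- pad[(h + dx) + seq_len(d[1]), (h + dy) + seq_len(d[2])]
    wr <- exp(-(nb - img)^2 / (2 * sigma_range^2))
    num <- num + ws * wr * nb
    den <- den + ws * wr
  }
  num / den
}

#' Segment tissue in a slice AIP
#'
#' Denoises with a bilateral filter, separates tissue from agarose/water by
#' Otsu thresholding (tissue = bright class), despeckles the mask with a
#' median filter and fills interior holes.
#'
#' @param aip Non-constant matrix (slice average intensity projection).
#' @param pixel_size_um Pixel size (um), stored as provenance.
#' @param sigma_spatial_px,median_radius_px Filter parameters.
#' @return An object of class `tissue_mask`: `mask` (logical matrix),
#'   `pixel_size_um`, `provenance`.
#' @export
segment_tissue <- function(aip, pixel_size_um = 25, sigma_spatial_px = 3,
                           median_radius_px = 2L) {
  stop_if(diff(range(aip)) <= 0, "degenerate input: constant image")
  sm <- bilateral_filter(aip, sigma_spatial_px = sigma_spatial_px)
  x01 <- norm01(sm)
  thr <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1))
  mask <- x01 > thr
  mask <- EBImage::medianFilter(EBImage::Image(mask * 1), median_radius_px) > 0.5
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  structure(list(mask = matrix(as.logical(mask), nrow(aip), ncol(aip)),
                 pixel_size_um = pixel_size_um,
                 provenance = list(sigma_spatial_px = sigma_spatial_px,
                                   otsu_threshold = as.numeric(thr),
                                   median_radius_px = median_radius_px)),
            class = "tissue_mask")
}

#' Probability bias map guiding automated ROI selection
#'
#' Sums the min-max normalized tissue AIP with the normalized absolute
#' deviation of pixel intensity from the mean intensity within the tissue
#' mask, smooths with a Gaussian (sigma in um; the 75 um kernel of the
#' acquisition), zeroes everything outside the mask, and normalizes the
#' result to sum to 1 over the mask. High values mark bright tissue or
#' contrast-rich areas (fibers); a degenerate (constant) feature map falls
#' back to a uniform distribution over the mask.
#'
#' @param aip Slice AIP matrix.
#' @param mask A [segment_tissue()] mask (or logical matrix).
#' @param sigma_um Gaussian smoothing sigma (um).
#' @param pixel_size_um Pixel size (um).
#' @return An object of class `probability_map`: `p` (matrix summing to 1
#'   over the mask, 0 outside), `mask`, `sigma_um`, `pixel_size_um`.
#' @export
probability_map <- function(aip, mask, sigma_um = 75, pixel_size_um = NULL) {
  if (inherits(mask, "tissue_mask")) {
    pixel_size_um <- pixel_size_um %||% mask$pixel_size_um
    mask <- mask$mask
  }
  pixel_size_um <- pixel_size_um %||% 25
  stop_if(!any(mask), "empty tissue mask")
  mvals <- aip[mask]
  f <- matrix(0, nrow(aip), ncol(aip))
  n1 <- aip; n1[!mask] <- NA
  r1 <- range(mvals)
  feat1 <- if (diff(r1) > 0) (aip - r1[1]) / diff(r1) else aip * 0
  dev <- abs(aip - mean(mvals))
  r2 <- range(dev[mask])
  feat2 <- if (diff(r2) > 0) (dev - r2[1]) / diff(r2) else dev * 0
  f[mask] <- feat1[mask] + feat2[mask]
  f <- gauss_smooth(f, sigma_um / pixel_size_um)
  f[!mask] <- 0
  f[f < 0] <- 0
  s <- sum(f)
  p <- if (s > 0) f / s else ifelse(mask, 1 / sum(mask), 0)
  structure(list(p = p, mask = mask, sigma_um = sigma_um,
                 pixel_size_um = pixel_size_um),
            class = "probability_map")
}

#' Candidate ROI centers satisfying the tissue-margin constraint
#'
#' Pixels whose Euclidean distance to the tissue boundary is at least
#' `margin_um` (the mask eroded by the margin).
#'
#' @param mask Logical matrix (or `tissue_mask`).
#' @param margin_um Minimum distance from the agarose/tissue boundary (um).
#' @param pixel_size_um Pixel size (um).
#' @return Logical matrix of admissible centers.
#' @export
roi_candidates <- function(mask, margin_um = 250, pixel_size_um = 25) {
  if (inherits(mask, "tissue_mask")) {
    pixel_size_um <- mask$pixel_size_um
    mask <- mask$mask
  }
  if (margin_um <= 0) return(mask)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  matrix(as.numeric(dm), nrow(mask), ncol(mask)) * pixel_size_um >= margin_um
}

#' Sample ROI positions from the probability map
#'
#' Draws ROI centers without replacement, weighted by the probability map,
#' from the margin-eroded candidate set, rejecting draws closer than
#' `min_separation_um` (center-to-center) to an already accepted ROI.
#' Rejection is capped at `100 * n` attempts; if the constraints exhaust the
#' candidates fewer ROIs are returned with a warning. Deterministic given
#' `seed`.
#'
#' @param pmap A [probability_map()].
#' @param mask A [segment_tissue()] mask (or logical matrix).
#' @param n Number of ROIs requested (>= 0).
#' @param margin_um Minimum distance from the tissue boundary (um).
#' @param min_separation_um Minimum center-to-center distance (um).
#' @param seed Integer seed.
#' @param fov_mm ROI field of view (mm).
#' @param slice_index Slice from which the ROIs are drawn.
#' @param z0_um First focal plane depth within the slice (um).
#' @param thickness_um OCM axial extent (um).
#' @param candidates Optional precomputed [roi_candidates()] matrix.
#' @return Data frame of class `roi_spec` with one row per accepted ROI:
#'   `label`, `x_um`, `y_um` (centers), `fov_mm`, `slice_index`, `z0_um`,
#'   `thickness_um`, `mode`.
#' @export
sample_rois <- function(pmap, mask, n, margin_um = 250, min_separation_um = 0,
                        seed = 1L, fov_mm = 0.5, slice_index = 0L,
                        z0_um = 0, thickness_um = 250, candidates = NULL) {
  stop_if(n < 0, "n must be >= 0")
  px <- pmap$pixel_size_um
  cand <- candidates %||% roi_candidates(mask, margin_um, px)
  empty <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      fov_mm = numeric(0), slice_index = integer(0),
                      z0_um = numeric(0), thickness_um = numeric(0),
                      mode = character(0))
  class(empty) <- c("roi_spec", "data.frame")
  if (n == 0) return(empty)
  idx <- which(cand & pmap$p > 0)
  stop_if(length(idx) == 0,
          "infeasible constraints: no candidate satisfies the margin")
  w <- pmap$p[idx]
  pos <- arrayInd(idx, dim(cand))
  xy <- (pos - 0.5) * px                       # pixel centers, um

  with_seed(seed, {
    accepted <- integer(0)
    alive <- rep(TRUE, length(idx))
    attempts <- 0L
    while (length(accepted) < n && any(alive) && attempts < 100L * n) {
      attempts <- attempts + 1L
      pool <- which(alive)
      j <- if (length(pool) == 1L) pool else
        pool[sample.int(length(pool), 1L, prob = w[pool])]
      alive[j] <- FALSE
      if (length(accepted) && min_separation_um > 0) {
        dmin <- min(sqrt((xy[accepted, 1] - xy[j, 1])^2 +
                           (xy[accepted, 2] - xy[j, 2])^2))
        if (dmin < min_separation_um) next
      }
      accepted <- c(accepted, j)
    }
    if (length(accepted) < n)
      warning("constraints exhausted the candidates: returning ",
              length(accepted), " of ", n, " ROIs")
    out <- data.frame(label = seq_along(accepted),
                      x_um = xy[accepted, 1], y_um = xy[accepted, 2],
                      fov_mm = fov_mm, slice_index = as.integer(slice_index),
                      z0_um = z0_um, thickness_um = thickness_um,
                      mode = "auto", stringsAsFactors = FALSE)
    class(out) <- c("roi_spec", "data.frame")
    out
  })
}

#' Is automated ROI selection scheduled on this slice?
#'
#' Selection runs every `every` slices (every fourth by default).
#'
#' @param slice_index Slice number (0-based, >= 0).
#' @param every Cadence (> 0).
#' @return TRUE iff `slice_index` is a multiple of `every`.
#' @export
schedule_rois <- function(slice_index, every = 4L) {
  stop_if(every <= 0, "`every` must be > 0")
  stop_if(any(slice_index < 0), "slice_index must be >= 0")
  slice_index %% every == 0
}
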