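# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Min-max normalization to [0, 1]; degenerate input maps to all zeros
#' @noRd
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Discrete Gaussian kernel (unit sum), half-width 4 sigma
#' @noRd
gauss_kernel <- function(sigma, spacing = 1) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma / spacing))
  u <- (-h:h) * spacing
  k <- exp(-u^2 / (2 * sigma^2))
  k / sum(k)
}

#' 1-D Gaussian smoothing with reflected edges
#' @noRd
gauss_smooth_1d <- function(x, sigma, spacing = 1) {
  k <- gauss_kernel(sigma, spacing)
  if (length(k) == 1L) return(x)
  h <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(x[pmin(h:1, n)], x, x[pmax(n - (1:h) + 1L, 1L)])
  stats::convolve(xp, rev(k), type = "filter")
}

#' Separable Gaussian smoothing of a 2-D or 3-D array (sigma in voxels)
#' @noRd
gauss_smooth <- function(a, sigma) {
  d <- dim(a)
  if (is.null(d)) return(gauss_smooth_1d(a, sigma))
  sigma <- rep_len(sigma, length(d))
  out <- a
  for (ax in seq_along(d)) {
    if (sigma[ax] <= 0) next
    out <- apply_along(out, ax, function(v) gauss_smooth_1d(v, sigma[ax]))
  }
  out
}

# apply FUN over 1-D fibres along axis `ax`, preserving shape
apply_along <- function(a, ax, FUN) {
  d <- dim(a)
  perm <- c(ax, seq_along(d)[-ax])
  m <- aperm(a, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  m <- apply(m, 2, FUN)
  dim(m) <- dm
  aperm(m, order(perm))
}

#' Trilinear interpolation of a 3-D array at physical points
#'
#' Voxel centers sit at (i - 0.5) * voxel_size (0-based physical frame,
#' half-open extents). Points outside the array return `fill`.
#' @noRd
interp3 <- function(a, x, y, z, voxel_size, fill = 0) {
  d <- dim(a)
  fx <- x / voxel_size[1] + 0.5
  fy <- y / voxel_size[2] + 0.5
  fz <- z / voxel_size[3] + 0.5
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  out <- numeric(length(fx)) + fill
  # gather with clamping; mark fully outside points
  inside <- fx >= 0.5 & fx <= d[1] + 0.5 & fy >= 0.5 & fy <= d[2] + 0.5 &
    fz >= 0.5 & fz <= d[3] + 0.5
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  g <- function(i, j, k) a[cbind(cl(i, d[1]), cl(j, d[2]), cl(k, d[3]))]
  v <- (1 - tx) * (1 - ty) * (1 - tz) * g(i0, j0, k0) +
    tx * (1 - ty) * (1 - tz) * g(i0 + 1, j0, k0) +
    (1 - tx) * ty * (1 - tz) * g(i0, j0 + 1, k0) +
    tx * ty * (1 - tz) * g(i0 + 1, j0 + 1, k0) +
    (1 - tx) * (1 - ty) * tz * g(i0, j0, k0 + 1) +
    tx * (1 - ty) * tz * g(i0 + 1, j0, k0 + 1) +
    (1 - tx) * ty * tz * g(i0, j0 + 1, k0 + 1) +
    tx * ty * tz * g(i0 + 1, j0 + 1, k0 + 1)
  out[inside] <- v[inside]
  out
}

#' Bilinear interpolation of a matrix at fractional (row, col) indices
#' (1-based index space); outside points return NA.
#' @noRd
interp2_idx <- function(m, ri, ci) {
  d <- dim(m)
  i0 <- floor(ri); j0 <- floor(ci)
  tx <- ri - i0; ty <- ci - j0
  inside <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  g <- function(i, j) m[cbind(cl(i, d[1]), cl(j, d[2]))]
  v <- (1 - tx) * (1 - ty) * g(i0, j0) + tx * (1 - ty) * g(i0 + 1, j0) +
    (1 - tx) * ty * g(i0, j0 + 1) + tx * ty * g(i0 + 1, j0 + 1)
  v[!inside] <- NA_real_
  v
}

# population standard deviation (divisor n)
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
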