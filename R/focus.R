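# Autofocus search, water/tissue interface detection, and focal-surface
# characterization by low-order Zernike polynomials.

#' Focus quality metric of an OCT volume
#'
#' Mean intensity of the A-line at the centre of the lateral field of view —
#' the quantity maximized by the autofocus.
#'
#' @param vol An [intensity_volume()].
#' @return Scalar metric.
#' @export
focus_metric <- function(vol) {
  d <- dim(vol$intensity)
  stop_if(is.null(d) || any(d < 1), "empty volume")
  mean(vol$intensity[, ceiling(d[2] / 2), ceiling(d[3] / 2)])
}

# Fibonacci numbers F(1..n), F(1) = F(2) = 1 (exact in doubles up to F(78))
fibonacci_numbers <- function(n) {
  f <- numeric(n)
  f[1] <- 1
  if (n >= 2) f[2] <- 1
  for (i in seq_len(n - 2) + 2) f[i] <- f[i - 1] + f[i - 2]
  f
}

#' Fibonacci search for a unimodal maximum
#'
#' Classical Fibonacci elimination on the bracket `[a, b]` spending exactly
#' `n_evals` metric evaluations; the final bracket length is
#' `(b - a) / F(n_evals + 1)` and the returned depth is its midpoint. The
#' last evaluation is the standard epsilon probe that resolves the degenerate
#' midpoint comparison.
#'
#' @param evaluate Function z -> scalar metric (must be finite).
#' @param bracket Initial interval `c(a, b)` with a < b.
#' @param n_evals Number of evaluations (>= 2).
#' @return An object of class `focus_result`: `best_z`, `bracket`,
#'   `n_evaluations`, `trace` (data frame of evaluated z and metric values).
#' @export
fibonacci_search <- function(evaluate, bracket, n_evals = 15L) {
  a <- bracket[1]; b <- bracket[2]
  stop_if(!(a < b), "bracket must satisfy a < b")
  stop_if(n_evals < 2, "n_evals must be >= 2")
  n <- as.integer(n_evals)
  fib <- fibonacci_numbers(n + 1L)
  L0 <- b - a
  zs <- ms <- numeric(0)
  ev <- function(z) {
    v <- evaluate(z)
    stop_if(!is.finite(v), "non-finite metric value; search aborted")
    zs <<- c(zs, z); ms <<- c(ms, v)
    v
  }
  m <- n
  if (m > 2) {
    x1 <- a + (b - a) * fib[m - 1] / fib[m + 1]
    x2 <- a + (b - a) * fib[m] / fib[m + 1]
    f1 <- ev(x1); f2 <- ev(x2)
    while (m > 2) {
      if (f1 > f2) {
        b <- x2; x2 <- x1; f2 <- f1
        m <- m - 1L
        if (m > 2) { x1 <- a + (b - a) * fib[m - 1] / fib[m + 1]; f1 <- ev(x1) }
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        m <- m - 1L
        if (m > 2) { x2 <- a + (b - a) * fib[m] / fib[m + 1]; f2 <- ev(x2) }
      }
    }
    cmid <- x1                                 # x1 == x2 == midpoint of [a, b]
    fmid <- f1
  } else {
    cmid <- (a + b) / 2
    fmid <- ev(cmid)
  }
  eps <- 1e-3 * (b - a)
  fprobe <- ev(min(cmid + eps, b))
  if (fprobe > fmid) a <- cmid else b <- cmid
  structure(list(best_z = (a + b) / 2, bracket = c(a, b),
                 n_evaluations = length(zs),
                 trace = data.frame(z = zs, metric = ms)),
            class = "focus_result")
}

#' Detect the water/tissue interface depth along one axial profile
#'
#' Convolves the axial intensity profile with the first derivative of a
#' Gaussian and returns the depth of the maximum response for the configured
#' edge polarity (`"rising"`: dark water above bright tissue, the ex vivo
#' default). A response below `threshold_rel` times the profile's dynamic
#' range means no interface.
#'
#' @param z_um Axial sample positions (um, increasing, >= 5 samples).
#' @param profile Mean intensity at each position.
#' @param sigma_um Derivative-of-Gaussian scale (um); defaults to the sample
#'   spacing (one coarse scan step).
#' @param polarity `"rising"` or `"falling"`.
#' @param threshold_rel Minimum edge response relative to the dynamic range.
#' @return Interface depth (um).
#' @export
detect_interface_depth <- function(z_um, profile, sigma_um = NULL,
                                   polarity = c("rising", "falling"),
                                   threshold_rel = 0.05) {
  polarity <- match.arg(polarity)
  stop_if(length(z_um) < 5 || length(profile) != length(z_um),
          "need >= 5 matched z samples")
  dz <- mean(diff(z_um))
  sigma_um <- sigma_um %||% dz
  rng <- diff(range(profile))
  if (rng <= 0) stop("no interface: flat profile", call. = FALSE)
  h <- max(1L, ceiling(3 * sigma_um / dz))
  u <- (-h:h) * dz
  g <- exp(-u^2 / (2 * sigma_um^2))
  dg <- (u / sigma_um^2) * g                   # derivative kernel
  dg <- dg / sum(abs(dg)) * 2                  # unit response to a unit step
  n <- length(profile)
  pp <- c(rep(profile[1], h), profile, rep(profile[n], h))
  # response(i) = sum_j p(i + j) * dg(j): positive on a rising (dark->bright) edge
  resp <- vapply(seq_len(n), function(i) sum(pp[i:(i + 2 * h)] * dg), 0)
  if (polarity == "falling") resp <- -resp
  if (max(resp) < threshold_rel * rng)
    stop("no interface: edge response below threshold", call. = FALSE)
  z_um[which.max(resp)]
}

#' Interface depth map across a volume
#'
#' Applies [detect_interface_depth()] to every lateral position of an
#' intensity volume (full axial sampling); positions where detection fails
#' are masked out.
#'
#' @param vol An [intensity_volume()].
#' @param sigma_um Derivative-of-Gaussian scale (um).
#' @return An object of class `interface_surface`: `depth_um` (nx x ny,
#'   NA where invalid), `valid`, `pixel_size_um`.
#' @export
interface_surface <- function(vol, sigma_um = NULL) {
  d <- dim(vol$intensity)
  z <- vol$z0_um + (seq_len(d[1]) - 1L) * vol$voxel_size_um[1]
  depth <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    depth[i, j] <- tryCatch(
      detect_interface_depth(z, vol$intensity[, i, j], sigma_um = sigma_um),
      error = function(e) NA_real_)
  }
  structure(list(depth_um = depth, valid = is.finite(depth),
                 pixel_size_um = vol$voxel_size_um[2]),
            class = "interface_surface")
}

# ANSI/OSA single-index Zernike basis, j = 0..5, orthonormal on the unit disk:
# piston, vertical tilt, horizontal tilt, oblique astigmatism, defocus,
# vertical astigmatism.
zernike_basis <- function(rho, theta) {
  cbind(Z0 = rep(1, length(rho)),
        Z1 = 2 * rho * sin(theta),
        Z2 = 2 * rho * cos(theta),
        Z3 = sqrt(6) * rho^2 * sin(2 * theta),
        Z4 = sqrt(3) * (2 * rho^2 - 1),
        Z5 = sqrt(6) * rho^2 * cos(2 * theta))
}

# map surface pixel centers to unit-disk polar coordinates
surface_disk_coords <- function(surface) {
  d <- dim(surface$depth_um)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  ii <- matrix(seq_len(d[1]), d[1], d[2])
  jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  x <- ii - cx; y <- jj - cy
  rmax <- sqrt(max(x^2 + y^2))
  list(rho = sqrt(x^2 + y^2) / rmax, theta = atan2(y, x))
}

#' Decompose an interface surface into Zernike polynomials (j <= 5)
#'
#' Least-squares projection of the valid surface heights, mapped to the unit
#' disk (radius = the farthest valid pixel from the grid centre), onto the
#' ANSI-ordered orthonormal Zernike terms Z0..Z5.
#'
#' @param surface An [interface_surface()] (or a plain matrix of heights).
#' @return An object of class `zernike_coeffs`: `coefficients` (named c0..c5),
#'   `normalized_abs` (|c_j| / sum |c_j|), `residual_rms`.
#' @export
zernike_decompose <- function(surface) {
  if (is.matrix(surface))
    surface <- structure(list(depth_um = surface, valid = is.finite(surface)),
                         class = "interface_surface")
  ok <- which(surface$valid)
  stop_if(length(ok) < 6, "need >= 6 valid surface points")
  pc <- surface_disk_coords(surface)
  B <- zernike_basis(pc$rho[ok], pc$theta[ok])
  qb <- qr(B)
  stop_if(qb$rank < 6, "rank-deficient Zernike design")
  h <- surface$depth_um[ok]
  cf <- qr.coef(qb, h)
  fit <- as.vector(B %*% cf)
  sa <- sum(abs(cf))
  structure(list(coefficients = stats::setNames(as.numeric(cf), paste0("c", 0:5)),
                 normalized_abs = if (sa > 0) abs(as.numeric(cf)) / sa else rep(0, 6),
                 residual_rms = sqrt(mean((h - fit)^2))),
            class = "zernike_coeffs")
}

#' Evaluate a Zernike expansion on a surface grid
#'
#' Reconstructs heights from coefficients c0..c5 on the pixel grid of `dim`,
#' using the same unit-disk mapping as [zernike_decompose()].
#'
#' @param coefficients Numeric length-6 (or a `zernike_coeffs`).
#' @param dim Grid size (nx, ny).
#' @export
zernike_surface <- function(coefficients, dim) {
  if (inherits(coefficients, "zernike_coeffs"))
    coefficients <- coefficients$coefficients
  fake <- structure(list(depth_um = matrix(0, dim[1], dim[2]),
                         valid = matrix(TRUE, dim[1], dim[2])),
                    class = "interface_surface")
  pc <- surface_disk_coords(fake)
  B <- zernike_basis(as.vector(pc$rho), as.vector(pc$theta))
  matrix(B %*% as.numeric(coefficients), dim[1], dim[2])
}
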