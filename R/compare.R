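# Multimodal OCT/dMRI comparison: OCM image features per ROI, quantile
# grouping by dMRI metric, and Bonferroni-corrected low-vs-high t-tests.

#' OCM image features of one ROI
#'
#' Normalized reflectivity (clipped to [0, 1] after division by the
#' brain-wide normalization reference) and the attenuation coefficient,
#' summarized by their mean and population standard deviation over the ROI
#' footprint.
#'
#' @param roi_aip ROI average intensity projection (matrix or vector).
#' @param roi_attenuation Per-A-line attenuation coefficients (mm^-1).
#' @param norm_reference Reflectivity normalization constant (> 0); the
#'   convention used throughout is the 99.9th percentile of all ROI AIP
#'   intensities in a brain, see [reflectivity_norm_reference()].
#' @return One-row data frame: `mean_rN`, `sd_rN`, `mean_mu`, `sd_mu`.
#' @export
ocm_features <- function(roi_aip, roi_attenuation, norm_reference) {
  stop_if(length(roi_aip) == 0 || length(roi_attenuation) == 0, "empty inputs")
  stop_if(norm_reference <= 0, "norm_reference must be > 0")
  rn <- pmin(pmax(as.numeric(roi_aip) / norm_reference, 0), 1)
  mu <- as.numeric(roi_attenuation)
  mu <- mu[is.finite(mu)]
  data.frame(mean_rN = mean(rn), sd_rN = sd_pop(rn),
             mean_mu = if (length(mu)) mean(mu) else NA_real_,
             sd_mu = sd_pop(mu))
}

#' Reflectivity normalization reference for a set of ROI AIPs
#'
#' @param aips List of ROI AIP matrices (or one array).
#' @param prob Upper quantile used as the reference (default 0.999).
#' @export
reflectivity_norm_reference <- function(aips, prob = 0.999) {
  v <- unlist(lapply(if (is.list(aips)) aips else list(aips), as.numeric))
  stats::quantile(v, prob, names = FALSE)
}

#' Quantile grouping of ROIs by a dMRI metric
#'
#' Cuts at the 25/50/75% sample quantiles (linear interpolation between order
#' statistics, R type 7) with half-open assignment: values <= q25 are Q1,
#' (q25, q50] Q2, (q50, q75] Q3, above q75 Q4.
#'
#' @param values Per-ROI metric values (>= 4 finite, not all identical).
#' @param probs Quantile probabilities.
#' @return An object of class `quantile_groups`: `group` (factor Q1..Q4,
#'   named by ROI when `values` is named), `cuts`.
#' @export
quantile_groups <- function(values, probs = c(0.25, 0.5, 0.75)) {
  v <- values[is.finite(values)]
  stop_if(length(v) < 4, "need >= 4 finite values")
  stop_if(diff(range(v)) <= 0, "degenerate grouping: all values identical")
  cuts <- stats::quantile(values, probs, na.rm = TRUE, names = FALSE, type = 7)
  g <- cut(values, c(-Inf, cuts, Inf), labels = paste0("Q", seq_len(length(cuts) + 1)),
           right = TRUE)
  if (!is.null(names(values))) names(g) <- names(values)
  structure(list(group = g, cuts = cuts), class = "quantile_groups")
}

#' Low-vs-high quantile t-tests of OCM features across dMRI metrics
#'
#' For every feature column and every metric, compares the ROIs in the lowest
#' quantile group (Q1, < 25%) with those in the highest (Q4, > 75%) by a
#' two-sample t-test (Welch by default; `pooled = TRUE` gives the classical
#' equal-variance test). Significance is declared at the Bonferroni-corrected
#' level `alpha / n_comparisons` — 0.05 / 20 = 0.0025 for the default
#' 4-feature x 5-metric design.
#'
#' @param features Data frame of per-ROI feature columns (one row per ROI).
#' @param groups Named list of [quantile_groups()] (or group factors), one
#'   per metric, aligned with the feature rows.
#' @param alpha Family-wise significance level.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return An object of class `group_test_result`: data frame `tests` with
#'   one row per (feature, metric) — t statistic, two-sided p, group
#'   means/sds/sizes, the corrected threshold and the significance flag —
#'   plus `alpha`, `n_comparisons`, `threshold`.
#' @export
low_high_ttests <- function(features, groups, alpha = 0.05, pooled = FALSE) {
  fcols <- names(features)
  mnames <- names(groups) %||% paste0("metric", seq_along(groups))
  n_comp <- length(fcols) * length(groups)
  thr <- alpha / n_comp
  rows <- list()
  for (m in seq_along(groups)) {
    g <- groups[[m]]
    if (inherits(g, "quantile_groups")) g <- g$group
    lo <- g == "Q1"; hi <- g == levels(g)[length(levels(g))]
    for (f in fcols) {
      x <- features[[f]][lo & !is.na(g)]
      y <- features[[f]][hi & !is.na(g)]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) {
        warning("group size < 2 for ", f, " x ", mnames[m], "; test skipped")
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, metric = mnames[m], t = NA_real_, p = NA_real_,
          mean_low = mean(x), mean_high = mean(y),
          sd_low = stats::sd(x), sd_high = stats::sd(y),
          n_low = length(x), n_high = length(y),
          threshold = thr, significant = NA)
        next
      }
      tt <- stats::t.test(y, x, var.equal = pooled)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, metric = mnames[m],
        t = unname(tt$statistic), p = tt$p.value,
        mean_low = mean(x), mean_high = mean(y),
        sd_low = stats::sd(x), sd_high = stats::sd(y),
        n_low = length(x), n_high = length(y),
        threshold = thr, significant = tt$p.value < thr)
    }
  }
  structure(list(tests = do.call(rbind, rows), alpha = alpha,
                 n_comparisons = n_comp, threshold = thr),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("low/high quantile t-tests: %d comparisons, threshold p < %g\n",
              x$n_comparisons, x$threshold))
  print(x$tests[, c("feature", "metric", "t", "p", "significant")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
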