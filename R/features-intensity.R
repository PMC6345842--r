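# Intensity-based feature families: local intensity (2), intensity
# statistics (18), intensity histogram (23, on discretised grey levels) and
# intensity-volume histogram (15, on re-segmented HU values at 1 HU
# resolution).

local_intensity_names <- c("local_intensity_peak", "global_intensity_peak")

stat_feature_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
  "p90", "maximum", "iqr", "range", "mean_abs_dev", "robust_mean_abs_dev",
  "median_abs_dev", "coeff_variation", "quartile_coeff_dispersion",
  "energy", "rms")

ih_feature_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
  "p90", "maximum", "mode", "iqr", "range", "mean_abs_dev",
  "robust_mean_abs_dev", "median_abs_dev", "coeff_variation",
  "quartile_coeff_dispersion", "entropy", "uniformity", "max_gradient",
  "max_gradient_level", "min_gradient", "min_gradient_level")

ivh_feature_names <- c(
  "v10", "v25", "v50", "v75", "v90", "i10", "i25", "i50", "i75", "i90",
  "v10_minus_v90", "v25_minus_v75", "i10_minus_i90", "i25_minus_i75", "auc")

# Mean intensity within a 1 cm^3 sphere centred on a voxel, evaluated for
# the intensity-peak features. The sphere uses all image voxels (also
# outside the ROI), truncated at the grid border.
local_intensity_features <- function(image, int_mask) {
  out <- stats::setNames(rep(NA_real_, 2), local_intensity_names)
  idx <- which(int_mask$labels)
  if (length(idx) == 0) return(out)
  sp <- image$spacing
  r <- (3 * 1000 / (4 * pi))^(1 / 3)  # radius of a 1 cm^3 sphere, mm
  steps <- lapply(1:3, function(ax) seq(-floor(r / sp[ax]), floor(r / sp[ax])))
  offs <- as.matrix(expand.grid(steps))
  keep <- rowSums(sweep(offs, 2, sp, "*")^2) <= r^2
  offs <- offs[keep, , drop = FALSE]

  d <- dim(image$voxels)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (rr in seq_len(nrow(offs))) {
    o <- offs[rr, ]
    sx <- shift_range(d[1], o[1]); sy <- shift_range(d[2], o[2])
    sz <- shift_range(d[3], o[3])
    acc[sx$dst, sy$dst, sz$dst] <- acc[sx$dst, sy$dst, sz$dst] +
      image$voxels[sx$src, sy$src, sz$src]
    cnt[sx$dst, sy$dst, sz$dst] <- cnt[sx$dst, sy$dst, sz$dst] + 1
  }
  sphere_mean <- acc / cnt
  vals <- image$voxels[idx]
  peaks <- sphere_mean[idx]
  out["global_intensity_peak"] <- max(peaks)
  gmax <- idx[vals == max(vals)]
  out["local_intensity_peak"] <- max(sphere_mean[gmax])
  out
}

# destination/source index ranges for an integer array shift by `off`
shift_range <- function(n, off) {
  if (off >= 0) {
    list(dst = seq_len(n - off), src = seq_len(n - off) + off)
  } else {
    list(dst = seq_len(n + off) - off, src = seq_len(n + off))
  }
}

stat_features <- function(x) {
  out <- stats::setNames(rep(NA_real_, length(stat_feature_names)),
                         stat_feature_names)
  n <- length(x)
  if (n == 0) return(out)
  mu <- mean(x)
  v <- mean((x - mu)^2)  # population variance per IBSI convention
  out["mean"] <- mu
  out["variance"] <- v
  out["skewness"] <- if (v > 0) mean((x - mu)^3) / v^1.5 else 0
  out["kurtosis"] <- if (v > 0) mean((x - mu)^4) / v^2 - 3 else 0
  out["median"] <- median(x)
  out["minimum"] <- min(x)
  qs <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  out["p10"] <- qs[1]
  out["p90"] <- qs[4]
  out["maximum"] <- max(x)
  out["iqr"] <- qs[3] - qs[2]
  out["range"] <- max(x) - min(x)
  out["mean_abs_dev"] <- mean(abs(x - mu))
  xr <- x[x >= qs[1] & x <= qs[4]]
  out["robust_mean_abs_dev"] <- if (length(xr)) mean(abs(xr - mean(xr))) else 0
  out["median_abs_dev"] <- mean(abs(x - median(x)))
  out["coeff_variation"] <- if (mu != 0) sqrt(v) / mu else NA_real_
  qsum <- qs[3] + qs[2]
  out["quartile_coeff_dispersion"] <-
    if (qsum != 0) (qs[3] - qs[2]) / qsum else NA_real_
  out["energy"] <- sum(x^2)
  out["rms"] <- sqrt(mean(x^2))
  out
}

# Intensity-histogram features over discretised grey levels g in 1..Ng.
ih_features <- function(g, n_levels) {
  out <- stats::setNames(rep(NA_real_, length(ih_feature_names)),
                         ih_feature_names)
  n <- length(g)
  if (n == 0) return(out)
  st <- stat_features(as.numeric(g))
  common <- c("mean", "variance", "skewness", "kurtosis", "median", "minimum",
              "p10", "p90", "maximum", "iqr", "range", "mean_abs_dev",
              "robust_mean_abs_dev", "median_abs_dev", "coeff_variation",
              "quartile_coeff_dispersion")
  out[common] <- st[common]
  counts <- tabulate(g, nbins = n_levels)
  p <- counts / n
  pm <- p[p > 0]
  modes <- which(counts == max(counts))
  out["mode"] <- min(modes)  # lowest level on ties, documented convention
  out["entropy"] <- -sum(pm * log2(pm))
  out["uniformity"] <- sum(p^2)
  if (n_levels >= 2) {
    grad <- (c(counts[-1], NA) - c(NA, counts[-n_levels])) / 2
    grad[1] <- counts[2] - counts[1]
    grad[n_levels] <- counts[n_levels] - counts[n_levels - 1]
    out["max_gradient"] <- max(grad)
    out["max_gradient_level"] <- which.max(grad)
    out["min_gradient"] <- min(grad)
    out["min_gradient_level"] <- which.min(grad)
  } else {
    out[c("max_gradient", "min_gradient")] <- 0
    out[c("max_gradient_level", "min_gradient_level")] <- 1
  }
  out
}

# Intensity-volume histogram at 1 HU resolution over the re-segmentation
# range. nu(i) = fraction of ROI voxels with intensity >= i; the intensity
# fraction of i maps the range [lo, hi] to [0, 1].
ivh_features <- function(x, config) {
  out <- stats::setNames(rep(NA_real_, length(ivh_feature_names)),
                         ivh_feature_names)
  n <- length(x)
  if (n == 0) return(out)
  lo <- config$resegment_range[1]
  hi <- config$resegment_range[2]
  grid <- seq(floor(lo), ceiling(hi), by = 1)
  nu <- vapply(grid, function(i) mean(x >= i), numeric(1))
  gamma <- (grid - lo) / (hi - lo)

  vol_at_int_frac <- function(f) {
    sel <- gamma >= f
    if (!any(sel)) return(0)
    nu[which(sel)[1]]
  }
  int_at_vol_frac <- function(f) {
    # largest intensity still covering at least fraction f of the volume,
    # expressed as intensity fraction of the range
    sel <- which(nu >= f)
    if (length(sel) == 0) return(0)
    gamma[max(sel)]
  }
  for (f in c(10, 25, 50, 75, 90)) {
    out[paste0("v", f)] <- vol_at_int_frac(f / 100)
    out[paste0("i", f)] <- int_at_vol_frac(f / 100)
  }
  out["v10_minus_v90"] <- out["v10"] - out["v90"]
  out["v25_minus_v75"] <- out["v25"] - out["v75"]
  out["i10_minus_i90"] <- out["i10"] - out["i90"]
  out["i25_minus_i75"] <- out["i25"] - out["i75"]
  out["auc"] <- mean(nu)
  out
}
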