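#' First-order intensity statistics
#'
#' The 22 "Intensity" features of the registry, computed from the raw HU
#' values inside the VOI. Variance and standard deviation use population
#' (1/n) moments; Entropy and Uniformity are computed on the 25-HU histogram
#' (bins anchored at the in-mask minimum, base-2 log); PeakPosition is the HU
#' bin centre of the modal histogram bin; Total Energy scales Energy by the
#' voxel volume in mm^3.
#'
#' @param vol An [image_volume()] or numeric 3D array of HU values.
#' @param mask Logical array of the same dimensions, nonempty.
#' @param bin_width Histogram bin width in HU for Entropy / Uniformity /
#'   PeakPosition (default 25).
#' @return Named numeric vector of the first-order features.
#' @export
#' @examples
#' v <- image_volume(array(c(1, 2, 3, 4), c(2, 2, 1)))
#' m <- array(TRUE, c(2, 2, 1))
#' first_order_features(v, m)[c("Intensity Mean", "Intensity Variance")]
first_order_features <- function(vol, mask, bin_width = 25) {
  check_mask(vol, mask)
  x <- as_volume_array(vol)[mask]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)           # population variance
  s <- sqrt(v)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)

  lab <- floor((x - min(x)) / bin_width)
  p <- tabulate(lab + 1L)
  p <- p[p > 0] / n
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)
  modal_bin <- which.max(tabulate(lab + 1L)) - 1L
  peak_pos <- min(x) + (modal_bin + 0.5) * bin_width

  xr <- round(x)
  tab <- table(xr)
  mode_val <- as.numeric(names(tab)[which.max(tab)])

  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 else 0
  voxvol <- prod(vol_spacing(vol))

  c("Intensity Mean" = mu,
    "Intensity Median" = stats::median(x),
    "Intensity Std" = s,
    "Intensity Variance" = v,
    "Intensity Energy" = sum(x^2),
    "Intensity Entropy" = entropy,
    "Intensity Uniformity" = uniformity,
    "Intensity Mean absolute deviation" = mean(abs(x - mu)),
    "Intensity Root mean square" = sqrt(mean(x^2)),
    "Intensity 25percent" = q[2],
    "Intensity 75percent" = q[3],
    "Intensity Maximum" = max(x),
    "Intensity PeakPosition" = peak_pos,
    "Intensity Minimum" = min(x),
    "Intensity Skewness" = skew,
    "Intensity Kurtosis" = kurt,
    "Intensity Range" = max(x) - min(x),
    "Intensity Interquartile range" = q[3] - q[2],
    "Intensity 10percent" = q[1],
    "Intensity 90percent" = q[4],
    "Intensity Mode" = mode_val,
    "Intensity Total Energy" = sum(x^2) * voxvol)
}
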