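## Intensity histogram features, computed on the raw HU values of the
## re-segmented (and resampled) ROI. Skewness is the Fisher moment
## coefficient; kurtosis is the non-excess (Pearson) form, so a normal
## distribution scores 3. SD uses the sample (n - 1) denominator.

#' Histogram (intensity) features
#'
#' The 17 first-order features of the signature, in registry order:
#' mean, SD, median, skewness, kurtosis, min, p10, p90, max, IQR, range,
#' mean absolute deviation, robust mean absolute deviation (restricted to
#' the p10--p90 window), median absolute deviation (mean absolute deviation
#' from the median), coefficient of variation, root mean square, energy.
#'
#' @param vol A [CTVolume-class] (resampled).
#' @param mask A re-segmented [RoiMask-class] with at least 2 voxels.
#' @return Named numeric vector of length 17.
#' @export
histogramFeatures <- function(vol, mask) {
  if (!identical(dim(intensities(vol)), dim(roiArray(mask))))
    stop("volume/mask geometry mismatch")
  x <- intensities(vol)[roiArray(mask)]
  if (length(x) < 2L) stop("ROI must contain at least 2 voxels")
  m <- mean(x)
  m2 <- mean((x - m)^2)                # population moments for shape
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  p10 <- unname(stats::quantile(x, 0.10))
  p90 <- unname(stats::quantile(x, 0.90))
  med <- stats::median(x)
  xr <- x[x >= p10 & x <= p90]
  vals <- c(
    mean = m,
    sd = stats::sd(x),
    median = med,
    skewness = skew,
    kurtosis = kurt,
    min = min(x),
    p10 = p10,
    p90 = p90,
    max = max(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    range = max(x) - min(x),
    meanAbsDev = mean(abs(x - m)),
    robustMeanAbsDev = if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    medianAbsDev = mean(abs(x - med)),
    coeffVariation = if (m != 0) stats::sd(x) / m else 0,
    rms = sqrt(mean(x^2)),
    energy = sum(x^2))
  stopifnot(identical(names(vals), histFeatureNames()))
  vals
}
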