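## First-order (histogram) features.

.histogramNames <- paste0("histogram_", c(
  "10Percentile", "90Percentile", "CV", "Energy", "Entropy", "IQR",
  "Kurtosis", "Maximum", "Mean", "MAD", "Median", "Minimum", "Mode",
  "Range", "RMAD", "RMS", "Skewness", "SD", "Uniformity", "Variance"
))

# fixed-width binning anchored at the minimum; levels 1..ng
.binLevels <- function(x, binWidth) {
  as.integer(floor((x - min(x)) / binWidth)) + 1L
}

#' Histogram features of ROI voxel intensities
#'
#' Computes the 20 first-order features over a vector of HU values.
#' Conventions: population (n) denominators for variance and the
#' standardised moments; kurtosis is non-excess (a normal sample gives
#' about 3); `CV = 100 * SD / mean`; robust MAD (`RMAD`) is the mean
#' absolute deviation of the values between the 10th and 90th percentiles
#' (inclusive); entropy (log2) and uniformity are computed over
#' fixed-width bins anchored at the minimum; the mode is the centre of
#' the most populated bin with ties resolved toward the lowest bin.
#' Percentiles interpolate linearly between order statistics.  At zero
#' variance, skewness and kurtosis are defined as 0; at zero mean, CV is
#' undefined and reported as `NaN` with a warning.
#'
#' @param hu Numeric vector of in-ROI HU values (length >= 1).
#' @param binWidth HU bin width for entropy/uniformity/mode (default 5).
#' @return Named numeric vector of the 20 `histogram_*` features.
#' @examples
#' histogramFeatures(c(40, 42, 44, 46, 48))
#' @export
histogramFeatures <- function(hu, binWidth = 5) {
  if (!length(hu)) stop("empty ROI")
  x <- as.numeric(hu)
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)   # population variance
  s <- sqrt(v)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)

  lev <- .binLevels(x, binWidth)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  binCounts <- tabulate(lev)
  modeBin <- which.max(binCounts)  # which.max takes the lowest on ties
  mode <- min(x) + (modeBin - 0.5) * binWidth

  cv <- if (mu == 0) {
    warning("CV undefined: mean intensity is zero")
    NaN
  } else 100 * s / mu

  robust <- x[x >= q[1] & x <= q[4]]
  rmad <- mean(abs(robust - mean(robust)))

  out <- c(
    q[1], q[4], cv, sum(x^2),
    -sum(p * log2(p)), q[3] - q[2],
    if (s > 0) mean((x - mu)^4) / v^2 else 0,
    max(x), mu, mean(abs(x - mu)), median(x), min(x), mode,
    max(x) - min(x), rmad, sqrt(mean(x^2)),
    if (s > 0) mean((x - mu)^3) / s^3 else 0,
    s, sum(p^2), v
  )
  names(out) <- .histogramNames
  out
}
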