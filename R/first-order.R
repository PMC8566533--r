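## First-order (histogram) statistics of the in-mask intensities. Entropy
## and uniformity use the same zero-anchored fixed-bin-width histogram rule
## as gray-level quantization; entropy is in bits.

.FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order statistics of an image within a mask
#'
#' Computes the 18 first-order features: energy (sum of squared
#' intensities), total energy (energy times voxel volume), histogram
#' entropy (bits) and uniformity (both on the fixed-bin-width histogram,
#' default width 25), minimum, 10th / 90th percentiles, maximum, mean,
#' median, interquartile range, range, mean absolute deviation, robust MAD
#' (within the 10-90 percentile band), root mean squared, skewness,
#' (Pearson) kurtosis and population variance.
#'
#' @param image a \linkS4class{VolumetricImage}.
#' @param mask a non-empty \linkS4class{RegionMask} on the same grid.
#' @param binWidth histogram bin width for entropy/uniformity.
#' @return Named numeric vector of length 18.
#' @export
firstOrderFeatures <- function(image, mask, binWidth = 25) {
  stopifnot(is(image, "VolumetricImage"), is(mask, "RegionMask"))
  x <- image@values[mask@values]
  n <- length(x)
  if (n == 0) stop("empty mask")

  ## zero-anchored fixed-width histogram probabilities
  lev <- floor(x / binWidth)
  p <- as.numeric(table(lev)) / n
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)

  mu <- mean(x)
  q <- as.numeric(stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90),
                                  type = 7))
  rob <- x[x >= q[1] & x <= q[5]]
  varp <- mean((x - mu)^2)
  sk <- if (varp > 0) mean((x - mu)^3) / varp^1.5 else 0
  ku <- if (varp > 0) mean((x - mu)^4) / varp^2 else 0

  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2) * prod(image@spacing),
    Entropy = entropy,
    Minimum = min(x),
    "10Percentile" = q[1],
    "90Percentile" = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = varp,
    Uniformity = uniformity)
}
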