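# First-order (intensity histogram) statistics of the masked voxels.

#' First-order intensity features
#'
#' The 18 standard first-order statistics of the masked voxel
#' intensities.  Moment-based statistics (variance, skewness, kurtosis)
#' use population central moments (denominator n); skewness and kurtosis
#' return 0 for a constant VOI.  `Entropy` and `Uniformity` are computed
#' on the fixed-bin-width gray-level histogram (see [discretize()]);
#' `Energy`/`TotalEnergy` on the raw intensities.
#'
#' @param values numeric vector of masked voxel intensities.
#' @param levels optional integer vector of discretized gray levels for
#'   the same voxels (required for `Entropy`/`Uniformity`; without it
#'   both are reported as `NA`).
#' @param voxel_volume voxel volume in mm^3 (for `TotalEnergy`).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, levels = NULL, voxel_volume = 1) {
  if (length(values) < 1) stop("empty VOI")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9),
                       names = FALSE, type = 7)
  inner <- values[values >= q[1] & values <= q[5]]
  if (!is.null(levels)) {
    p <- tabulate(levels) / n
    entropy <- ent2(p)
    uniformity <- sum(p^2)
  } else {
    entropy <- NA_real_; uniformity <- NA_real_
  }
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = entropy,
    Minimum = min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = uniformity)
}

#' Skewness of masked intensities
#'
#' Population third standardized moment, 0 for a constant input.
#'
#' @param values numeric vector.
#' @export
skewness <- function(values) {
  unname(first_order_features(values)["Skewness"])
}

first_order_names <- function()
  c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
    "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
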