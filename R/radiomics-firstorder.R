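# First-order (intensity) statistics of the HU values inside the PCAT mask.
# Entropy and uniformity are computed on the discretized gray levels and
# therefore depend on the bin setting; all other features are bin independent.

FIRSTORDER_FEATURES <- c(
  "energy", "entropy", "minimum", "percentile10", "percentile90", "maximum",
  "mean", "median", "interquartile_range", "range",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "root_mean_square", "skewness", "kurtosis", "variance", "uniformity")

#' First-order intensity features
#'
#' Seventeen statistics of the raw HU distribution inside the mask. Skewness
#' and (Pearson) kurtosis are defined as 0 for a constant input; variance is
#' the population variance. Entropy (bits) and uniformity are computed on
#' the supplied discretized levels.
#'
#' @param hu_values numeric vector of in-mask HU values (nonempty).
#' @param levels integer vector of discretized levels for the same voxels.
#' @return named numeric vector of length 17.
#' @export
first_order_features <- function(hu_values, levels) {
  stopifnot(length(hu_values) >= 1L, length(levels) == length(hu_values))
  x <- hu_values
  out <- stats::setNames(numeric(length(FIRSTORDER_FEATURES)),
                         FIRSTORDER_FEATURES)
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  p <- tabulate(levels) / n
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  mid <- x[x >= q[1] & x <= q[5]]

  out["energy"] <- sum(x^2)
  out["entropy"] <- -sum(xlog2x(p))
  out["minimum"] <- min(x)
  out["percentile10"] <- q[1]
  out["percentile90"] <- q[5]
  out["maximum"] <- max(x)
  out["mean"] <- m
  out["median"] <- q[3]
  out["interquartile_range"] <- q[4] - q[2]
  out["range"] <- max(x) - min(x)
  out["mean_absolute_deviation"] <- mean(abs(x - m))
  out["robust_mean_absolute_deviation"] <-
    if (length(mid)) mean(abs(mid - mean(mid))) else 0
  out["root_mean_square"] <- sqrt(mean(x^2))
  out["skewness"] <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  out["kurtosis"] <- if (v > 0) mean((x - m)^4) / v^2 else 0
  out["variance"] <- v
  out["uniformity"] <- sum(p^2)
  out
}
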