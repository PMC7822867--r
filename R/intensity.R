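#' First-order histogram features
#'
#' The 11 first-order statistics of a VOI value vector: excess (Fisher)
#' kurtosis by default, maximum, mean, median, minimum, the 10th/25th/75th/
#' 90th percentiles (linear interpolation), skewness and standard
#' deviation. A constant input yields skewness 0 and kurtosis per the
#' selected convention (0 excess / 3 Pearson).
#'
#' @param values numeric vector (>= 2 values; for T2W pass normalized
#'   pseudo-T2 values, for ADC the unnormalized map values, both after
#'   outlier exclusion).
#' @param prefix optional name prefix, e.g. `"t2w_"` or `"adc_"`.
#' @param kurtosisType `"excess"` (Fisher, default) or `"pearson"`.
#' @return named numeric vector of length 11.
#' @examples
#' histogramFeatures(c(1, 2, 3, 4, 5))[c("mean", "p25", "p75")]
#' @export
histogramFeatures <- function(values, prefix = "",
                              kurtosisType = c("excess", "pearson")) {
  kurtosisType <- match.arg(kurtosisType)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  n <- length(values)
  mu <- mean(values)
  s <- stats::sd(values)
  cent <- values - mu
  if (s > 0) {
    m2 <- mean(cent^2)
    skew <- mean(cent^3) / m2^1.5
    kurt <- mean(cent^4) / m2^2
  } else {
    skew <- 0
    kurt <- 3
  }
  if (kurtosisType == "excess") kurt <- kurt - 3
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  out <- c(kurtosis = kurt, maximum = max(values), mean = mu,
           median = q[3], minimum = min(values),
           p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
           skewness = skew, sd = s)
  names(out) <- paste0(prefix, names(out))
  out
}
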