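# First-order (histogram) statistics of patch intensities: the
# intensity histogram and the moments derived from it -- mean,
# population variance, skewness and excess kurtosis -- plus min/max.

#' Intensity histogram of integer-leveled pixel values
#'
#' Tallies exact occurrences per level and normalizes by the total
#' pixel count, so the probabilities always sum to 1.
#'
#' @param values integer pixel levels in `0..L-1` (vector, matrix, or
#'   an integer-leveled [gray_image()]).
#' @param L number of levels.
#' @return an object of class `intensity_histogram` with fields
#'   `counts` (length `L`), `probs`, `L` and `n_pixels`.
#' @export
intensity_histogram <- function(values, L) {
  if (inherits(values, "gray_image")) {
    stopifnot(!values$normalized)
    L <- values$levels
    values <- values$pixels
  }
  v <- as.vector(values)
  if (length(v) == 0L) {
    stop("intensity_histogram: needs at least one pixel", call. = FALSE)
  }
  stopifnot(L >= 2, all(v == floor(v)), min(v) >= 0, max(v) <= L - 1)
  counts <- tabulate(v + 1L, nbins = as.integer(L))
  structure(
    list(counts = counts, probs = counts / length(v), L = as.integer(L),
         n_pixels = length(v)),
    class = "intensity_histogram"
  )
}

#' First-order statistics of a set of intensities
#'
#' Moments are computed over the empirical distribution of the supplied
#' values (population convention, weights 1/n): mean, variance,
#' skewness and *excess* kurtosis (the normal distribution scores 0),
#' plus min and max.  For a constant input the variance is 0 and
#' skewness/kurtosis are reported as 0 by policy, so degenerate patches
#' flow through the pipeline instead of erroring.
#'
#' @param values numeric intensities (vector, matrix, or a normalized
#'   [gray_image()]); typically on `[0, 1]`.
#' @return a named list of class `first_order_features` with entries
#'   `mean`, `variance`, `skewness`, `kurtosis`, `min`, `max`.
#' @export
first_order_features <- function(values) {
  if (inherits(values, "gray_image")) values <- values$pixels
  v <- as.vector(values)
  if (length(v) == 0L) {
    stop("first_order_features: needs at least one pixel", call. = FALSE)
  }
  mu <- mean(v)
  dev <- v - mu
  s2 <- mean(dev^2)
  if (s2 > 0) {
    skew <- mean(dev^3) / s2^1.5
    kurt <- mean(dev^4) / s2^2 - 3
  } else {
    skew <- 0 # degenerate-case policy: constant input
    kurt <- 0
  }
  structure(
    list(mean = mu, variance = s2, skewness = skew, kurtosis = kurt,
         min = min(v), max = max(v)),
    class = "first_order_features"
  )
}
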