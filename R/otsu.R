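#' Otsu threshold of a numeric sample
#'
#' Computes the threshold that maximises the between-class variance of a
#' two-class split of `x`, on a fixed-width histogram between `min(x)` and
#' `max(x)`. Unlike image-specific implementations this operates on any
#' numeric vector, which the compaction pipeline needs twice: once on raw
#' chromatin intensities (nucleus vs background) and once on Sobel gradient
#' magnitudes restricted to the nuclear mask (edge vs non-edge). Because the
#' histogram is built on the data's own range, the resulting classification
#' is invariant to affine intensity rescaling.
#'
#' @param x numeric vector (finite values; at least two distinct values).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value; pixels strictly greater than it fall in the
#'   upper (foreground/edge) class.
#' @examples
#' x <- c(rnorm(300, 10, 1), rnorm(300, 50, 2))
#' th <- otsu_threshold(x)
#' th > 15 && th < 45
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    abort("otsu_threshold() needs at least two finite values.", class = "chromdyn_error")
  }
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    abort("otsu_threshold() is undefined for constant input.", class = "chromdyn_error")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  # between-class variance for split after bin k
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(sigma_b)
  edges[k + 1L]
}
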