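#' @include utils.R
NULL

#' Otsu threshold of a real-valued map
#'
#' Min-max scales the input, accumulates a `bins`-bin histogram and returns
#' the bin edge (on the original value scale) that maximizes the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2`. Ties are broken towards
#' the smallest threshold. Pixels strictly above the returned threshold form
#' the foreground.
#'
#' @param x numeric vector, matrix or [ChromaticMap-class] with at least two
#'   distinct values.
#' @param bins histogram bin count (default 256).
#' @return the threshold on the original value scale, with attribute
#'   `betweenVariance` (the attained maximum, on the scaled histogram).
#' @examples
#' v <- c(rep(0.1, 8), rep(0.9, 8))
#' t <- otsuThreshold(v)         # separates the two groups exactly
#' all((v > t) == (v > 0.5))
#' @export
otsuThreshold <- function(x, bins = 256L) {
  if (is(x, "ChromaticMap")) x <- x@data
  v <- as.vector(x)
  if (!all(is.finite(v))) stop("values must be finite")
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) stop("degenerate histogram: input is constant")
  bins <- as.integer(bins)
  scaled <- (v - lo) / (hi - lo)
  counts <- tabulate(pmin(floor(scaled * bins), bins - 1L) + 1L, nbins = bins)
  n <- length(v)
  lev <- 0:(bins - 1L)
  w0 <- cumsum(counts)[1:(bins - 1L)]
  s0 <- cumsum(counts * lev)[1:(bins - 1L)]
  w1 <- n - w0
  sTot <- sum(counts * lev)
  valid <- w0 > 0L & w1 > 0L
  mu0 <- s0 / pmax(w0, 1L)
  mu1 <- (sTot - s0) / pmax(w1, 1L)
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)          # first maximum = smallest threshold
  thr <- lo + (k / bins) * (hi - lo)
  attr(thr, "betweenVariance") <- bcv[k]
  thr
}
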