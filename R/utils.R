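#' @include AllClasses.R
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Channel plane of an H x W x 3 array as a matrix (robust to 1-px images).
chPlane <- function(d, i) matrix(d[, , i], dim(d)[1L], dim(d)[2L])

# Disc-shaped structuring element of the given pixel radius.
discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Reflect (symmetric) folding of 0-based indices into 0..n-1; valid for any
# offset, including kernels wider than the image.
reflectIndex <- function(i, n) {
  m <- i %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m >= n, 2L * n - 1L - m, m)
}

# Dense n x n operator applying a 1-D normalized Gaussian of scale `sigma`
# with symmetric boundary reflection. Separable 2-D blur is then
# A_rows %*% X %*% t(A_cols); exact (up to kernel truncation at 4*sigma) and
# fast through BLAS for the image sizes used here.
.blurOpCache <- new.env(parent = emptyenv())

blurOperator <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  hit <- .blurOpCache[[key]]
  if (!is.null(hit)) return(hit)
  radius <- max(1L, as.integer(ceiling(4 * sigma)))
  taps <- (-radius):radius
  w <- exp(-0.5 * (taps / sigma)^2)
  w <- w / sum(w)
  A <- matrix(0, n, n)
  rows0 <- 0:(n - 1L)
  for (k in seq_along(taps)) {
    src <- reflectIndex(rows0 + taps[k], n)
    idx <- cbind(rows0 + 1L, src + 1L)
    A[idx] <- A[idx] + w[k]
  }
  .blurOpCache[[key]] <- A
  A
}

# Separable Gaussian blur of a matrix with reflected boundaries.
gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  A <- blurOperator(nrow(x), sigma)
  B <- blurOperator(ncol(x), sigma)
  A %*% x %*% t(B)
}

# Zero-mean, unit-variance Gaussian random field with correlation length
# `sigma` (px); sigma = 0 gives white noise. Consumes the current RNG stream.
smoothNoise <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) z <- gaussianBlur(z, sigma)
  s <- sd(as.vector(z))
  if (s == 0) return(matrix(0, h, w))
  (z - mean(z)) / s
}

# Internal: matrix -> EBImage grayscale Image and back. EBImage stores (x, y);
# disc brushes are symmetric so morphology commutes with the transpose and
# matrices can be passed through directly.
asImage <- function(m) EBImage::Image(m)

stopIfNot01 <- function(x, what) {
  if (any(!is.finite(x)) || min(x) < 0 || max(x) > 1)
    stop(sprintf("%s must be finite and in [0, 1]", what), call. = FALSE)
  invisible(TRUE)
}
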