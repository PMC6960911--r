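# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each quantity with naive enumeration, separate from
# the package's implementation paths.

# Otsu: scan every candidate bin edge, recomputing class masses and means
# from scratch at each split.
bruteOtsu <- function(v, bins = 256L) {
  lo <- min(v); hi <- max(v)
  scaled <- (v - lo) / (hi - lo)
  idx <- pmin(floor(scaled * bins), bins - 1L)
  counts <- tabulate(idx + 1L, nbins = bins)
  n <- length(v)
  best <- -Inf; bestK <- NA_integer_
  for (k in 1:(bins - 1L)) {
    left <- counts[1:k]; right <- counts[(k + 1L):bins]
    w0 <- sum(left); w1 <- sum(right)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:(k - 1L)) * left) / w0
    mu1 <- sum((k:(bins - 1L)) * right) / w1
    bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; bestK <- k }
  }
  lo + (bestK / bins) * (hi - lo)
}

# GLCM: accumulate co-occurrences pixel by pixel, then evaluate each
# statistic by explicit double sums.
bruteGlcm <- function(gray, k = 16L, directions = c("0", "45", "90", "135")) {
  rng <- range(gray)
  q <- if (rng[2] - rng[1] <= 0) {
    matrix(0L, nrow(gray), ncol(gray))
  } else {
    matrix(pmin(as.integer(floor((gray - rng[1]) / (rng[2] - rng[1]) * k)),
                k - 1L), nrow(gray), ncol(gray))
  }
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  G <- matrix(0, k, k)
  for (d in directions) {
    o <- offs[[d]]
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        a <- q[r, cc]; b <- q[r2, c2]
        G[a + 1, b + 1] <- G[a + 1, b + 1] + 1
        G[b + 1, a + 1] <- G[b + 1, a + 1] + 1
      }
    }
  }
  G <- G / sum(G)
  con <- 0; asm <- 0; ent <- 0; idm <- 0
  ui <- 0; vj <- 0
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    p <- G[i + 1, j + 1]
    con <- con + (i - j)^2 * p
    asm <- asm + p^2
    if (p > 0) ent <- ent - p * log10(p)
    idm <- idm + p / (1 + (i - j)^2)
    ui <- ui + i * p; vj <- vj + j * p
  }
  si2 <- 0; sj2 <- 0; sij <- 0
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    p <- G[i + 1, j + 1]
    si2 <- si2 + (i - ui)^2 * p
    sj2 <- sj2 + (j - vj)^2 * p
    sij <- sij + i * j * p
  }
  cor <- if (si2 > 0 && sj2 > 0) (sij - ui * vj) / sqrt(si2 * sj2) else 0
  c(glcm_con = con, glcm_asm = asm, glcm_ent = ent, glcm_idm = idm,
    glcm_cor = cor)
}

# Uniform LBP: per-pixel loop, explicit bilinear interpolation, string-based
# uniformity test.
bruteLbp <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  ang <- 2 * pi * (0:7) / 8
  hist <- numeric(59)
  uniformCodes <- Filter(function(x) {
    b <- as.integer(intToBits(x)[1:8])
    sum(b != c(b[-1], b[1])) <= 2
  }, 0:255)
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    code <- 0
    for (kk in 1:8) {
      x <- cc + cos(ang[kk]); y <- r + sin(ang[kk])
      x0 <- floor(x); y0 <- floor(y)
      fx <- x - x0; fy <- y - y0
      val <- gray[y0, x0] * (1 - fx) * (1 - fy)
      if (fx > 0) val <- val + gray[y0, x0 + 1] * fx * (1 - fy)
      if (fy > 0) val <- val + gray[y0 + 1, x0] * (1 - fx) * fy
      if (fx > 0 && fy > 0) val <- val + gray[y0 + 1, x0 + 1] * fx * fy
      if (val >= gray[r, cc] - 1e-12) code <- code + 2^(kk - 1)
    }
    pos <- match(code, uniformCodes)
    if (is.na(pos)) pos <- 59
    hist[pos] <- hist[pos] + 1
  }
  hist / sum(hist)
}

# Maximum inner rectangle: enumerate every axis-aligned rectangle.
bruteMaxRect <- function(mask) {
  best <- 0
  h <- nrow(mask); w <- ncol(mask)
  for (r1 in 1:h) for (r2 in r1:h) for (c1 in 1:w) for (c2 in c1:w) {
    if (all(mask[r1:r2, c1:c2])) {
      area <- (r2 - r1 + 1) * (c2 - c1 + 1)
      if (area > best) best <- area
    }
  }
  best
}

# Mann-Whitney AUC with ties counted half.
bruteAucU <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  100 * u / (length(pos) * length(neg))
}

# A uniform color patch as an RGBImage.
uniformImage <- function(h, w, rgb) {
  a <- array(0, c(h, w, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  RGBImage(a)
}

# Random in-gamut image.
randomImage <- function(h, w, seed) {
  set.seed(seed)
  RGBImage(array(runif(h * w * 3), c(h, w, 3)))
}

greenRGB <- c(0.125, 0.5, 0.125)   # exact binary fractions, hue 2*pi/3
soilRGB <- c(0.5, 0.3, 0.2)

# A small, quick scene spec for unit tests (not the study-scale default).
tinySceneSpec <- function(seed, nTrees = 4L, size = 256L, greenTarget = 0.3,
                          ...) {
  sceneSpec(width = size, height = size, nTrees = nTrees,
            greenTarget = greenTarget, seed = seed, ...)
}
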