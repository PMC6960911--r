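#' @include color.R regions.R
NULL

#' Canonical feature column order
#'
#' The fixed 78-name column order of every descriptor matrix: mean/variance
#' pairs of R, G, B, H, S, a*, b*, the five GLCM statistics, then the 59 LBP
#' bins.
#'
#' @return character vector of length 78.
#' @export
featureNames78 <- function() {
  ch <- c("R", "G", "B", "H", "S", "a", "b")
  c(as.vector(rbind(paste0("mean_", ch), paste0("var_", ch))),
    paste0("glcm_", c("con", "asm", "ent", "idm", "cor")),
    sprintf("lbp_%02d", 1:59))
}

#' Per-region color statistics (14 dimensions)
#'
#' Mean and population variance of R, G, B, hue, saturation, a* and b* over
#' the masked pixels, in that fixed order. Hue is an angle, so its mean and
#' variance are circular: the mean is the argument of the resultant vector
#' (mapped to `[0, 2*pi)`) and the variance is `1 - |resultant|` (in
#' `[0, 1]`).
#'
#' @param img an [RGBImage-class].
#' @param mask logical matrix selecting the region (>= 2 pixels).
#' @param hsi,lab optional precomputed [HSIImage-class] / [LabImage-class]
#'   for `img`, to avoid repeated conversion when looping over regions.
#' @return named numeric vector of length 14.
#' @export
colorFeatures <- function(img, mask, hsi = NULL, lab = NULL) {
  stopifnot(is(img, "RGBImage"))
  idx <- which(mask)
  if (length(idx) < 2L) stop("color features need at least 2 pixels")
  if (is.null(hsi)) hsi <- rgbToHsi(img)
  if (is.null(lab)) lab <- rgbToLab(img)
  popVar <- function(v) mean((v - mean(v))^2)
  stat <- function(v) c(mean(v), popVar(v))
  h <- hsi@hue[idx]
  resC <- mean(cos(h)); resS <- mean(sin(h))
  hMean <- atan2(resS, resC) %% (2 * pi)
  hVar <- 1 - sqrt(resC^2 + resS^2)
  out <- c(stat(img@data[, , 1L][idx]),
           stat(img@data[, , 2L][idx]),
           stat(img@data[, , 3L][idx]),
           hMean, hVar,
           stat(hsi@sat[idx]),
           stat(lab@a[idx]),
           stat(lab@b[idx]))
  names(out) <- featureNames78()[1:14]
  out
}

# Direction offsets (drow, dcol) for distance-1 co-occurrences.
.glcmOffsets <- list("0"   = c(0L, 1L),
                     "45"  = c(-1L, 1L),
                     "90"  = c(-1L, 0L),
                     "135" = c(-1L, -1L))

#' Gray-level co-occurrence statistics (5 dimensions)
#'
#' Quantizes a grayscale rectangle to `k` levels (uniform min-max bins;
#' constant input maps to level 0), accumulates symmetric distance-1
#' co-occurrences over the requested directions, normalizes to probabilities
#' G(i, j), and returns contrast `CON = sum (i-j)^2 G`, energy
#' `ASM = sum G^2`, entropy `ENT = -sum G lg G` (base-10, `0 lg 0 = 0`),
#' inverse difference moment `IDM = sum G / (1 + (i-j)^2)`, and correlation
#' `COR = (sum i j G - u_i u_j) / (s_i s_j)` with `COR = 0` when either
#' marginal variance vanishes.
#'
#' @param gray numeric matrix (at least 2 x 2).
#' @param k number of gray levels (default 16).
#' @param directions subset of `c("0", "45", "90", "135")` (degrees).
#' @return named numeric vector `(glcm_con, glcm_asm, glcm_ent, glcm_idm,
#'   glcm_cor)`.
#' @export
glcmFeatures <- function(gray, k = 16L,
                         directions = c("0", "45", "90", "135")) {
  if (!is.matrix(gray) || nrow(gray) < 2L || ncol(gray) < 2L)
    stop("GLCM needs a rectangle of at least 2 x 2 pixels")
  directions <- match.arg(directions, names(.glcmOffsets), several.ok = TRUE)
  k <- as.integer(k)
  rng <- range(gray)
  q <- if (rng[2L] - rng[1L] <= 0) {
    matrix(0L, nrow(gray), ncol(gray))
  } else {
    matrix(pmin(as.integer(floor((gray - rng[1L]) / (rng[2L] - rng[1L]) * k)),
                k - 1L), nrow(gray), ncol(gray))
  }
  h <- nrow(q); w <- ncol(q)
  counts <- numeric(k * k)
  for (d in directions) {
    off <- .glcmOffsets[[d]]
    r1 <- max(1L, 1L - off[1L]):min(h, h - off[1L])
    c1 <- max(1L, 1L - off[2L]):min(w, w - off[2L])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1L], c1 + off[2L], drop = FALSE]
    counts <- counts + tabulate(a * k + b + 1L, nbins = k * k) +
                       tabulate(b * k + a + 1L, nbins = k * k)
  }
  G <- matrix(counts / sum(counts), k, k, byrow = TRUE)  # G[i+1, j+1] = P(i, j)
  iL <- matrix(0:(k - 1L), k, k)
  jL <- t(iL)
  con <- sum((iL - jL)^2 * G)
  asm <- sum(G^2)
  pos <- G > 0
  ent <- -sum(G[pos] * log10(G[pos]))
  idm <- sum(G / (1 + (iL - jL)^2))
  ui <- sum(iL * G); vj <- sum(jL * G)
  si <- sqrt(sum((iL - ui)^2 * G)); sj <- sqrt(sum((jL - vj)^2 * G))
  cor <- if (si * sj > 0) (sum(iL * jL * G) - ui * vj) / (si * sj) else 0
  c(glcm_con = con, glcm_asm = asm, glcm_ent = ent, glcm_idm = idm,
    glcm_cor = cor)
}

# Uniform LBP code table: 256 -> bin 1..59 (58 uniform patterns in ascending
# code order, bin 59 pools all non-uniform codes).
.lbpTable <- local({
  codes <- 0:255
  bits <- sapply(codes, function(x) as.integer(intToBits(x)[1:8]))
  trans <- colSums(bits != bits[c(2:8, 1), , drop = FALSE])
  uniform <- trans <= 2L
  tab <- integer(256)
  tab[uniform] <- seq_len(sum(uniform))
  tab[!uniform] <- 59L
  tab
})

# Neighbor sampling offsets for P = 8, R = 1: angle 2*pi*k/8, k = 0..7,
# (dx, dy) = (R cos, R sin), y down the rows. Diagonals are bilinear.
.lbpOffsets <- cbind(dx = cos(2 * pi * (0:7) / 8),
                     dy = sin(2 * pi * (0:7) / 8))

#' Uniform local binary pattern histogram (59 dimensions)
#'
#' 8-neighbour LBP at radius 1 with bilinear sampling of the diagonal
#' neighbours; a bit is set when the neighbour is greater than or equal to
#' the centre, so the code is unchanged by adding any constant to the patch
#' (the descriptor's grayscale invariance). Patterns with at most two
#' circular 0/1 transitions occupy 58 bins in ascending code order; all other
#' patterns pool into bin 59. Border pixels have no full neighbourhood and
#' are skipped. The histogram is normalized to sum 1.
#'
#' @param gray numeric matrix (at least 3 x 3).
#' @return numeric vector of length 59 summing to 1 (names `lbp_01..lbp_59`).
#' @export
lbpHistogram <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L)
    stop("LBP needs a rectangle of at least 3 x 3 pixels")
  h <- nrow(gray); w <- ncol(gray)
  rows <- 2:(h - 1L); cols <- 2:(w - 1L)
  centre <- gray[rows, cols, drop = FALSE]
  code <- matrix(0L, length(rows), length(cols))
  for (kbit in 1:8) {
    dx <- .lbpOffsets[kbit, "dx"]; dy <- .lbpOffsets[kbit, "dy"]
    fx <- floor(dx); fy <- floor(dy)
    ax <- dx - fx; ay <- dy - fy
    samp <- 0
    for (byy in 0:1) for (bxx in 0:1) {
      wgt <- (if (bxx == 0) 1 - ax else ax) * (if (byy == 0) 1 - ay else ay)
      if (wgt == 0) next
      samp <- samp + wgt *
        gray[rows + fy + byy, cols + fx + bxx, drop = FALSE]
    }
    code <- code + bitwShiftL(1L, kbit - 1L) * (samp >= centre - 1e-12)
  }
  bins <- .lbpTable[code + 1L]
  hist <- tabulate(bins, nbins = 59L)
  out <- hist / sum(hist)
  names(out) <- sprintf("lbp_%02d", 1:59)
  out
}

#' Full 78-dimensional descriptor of one region
#'
#' Color statistics are taken over the complete region mask; texture (GLCM +
#' LBP) over the region's maximum inner rectangle (`mode = "inner_rect"`,
#' segmentation time) or over the region's bounding box (`mode =
#' "full_mask"`, used for rectangular training patches where the bounding box
#' is the patch itself). The texture gray plane is the HSI intensity.
#'
#' @param img an [RGBImage-class].
#' @param rs a [RegionSet-class].
#' @param id region id in `rs`.
#' @param mode `"inner_rect"` or `"full_mask"`.
#' @param hsi,lab optional precomputed conversions of `img`.
#' @param k GLCM gray-level count.
#' @return named numeric vector of length 78, or `NULL` (with a message) if
#'   the region's texture support is smaller than 3 x 3.
#' @export
regionFeatureVector <- function(img, rs, id, mode = c("inner_rect", "full_mask"),
                                hsi = NULL, lab = NULL, k = 16L) {
  mode <- match.arg(mode)
  stopifnot(is(img, "RGBImage"), is(rs, "RegionSet"))
  if (is.null(hsi)) hsi <- rgbToHsi(img)
  if (is.null(lab)) lab <- rgbToLab(img)
  mask <- rs@labelMap == id
  if (sum(mask) < 2L) {
    message("region ", id, " has fewer than 2 pixels; not featurizable")
    return(NULL)
  }
  rect <- if (mode == "inner_rect") {
    maxInnerRectangle(rs, id)
  } else {
    reg <- rs@regions[rs@regions$id == id, ]
    c(rowMin = reg$rowMin, colMin = reg$colMin,
      rowMax = reg$rowMax, colMax = reg$colMax)
  }
  if (rect["rowMax"] - rect["rowMin"] < 2L || rect["colMax"] - rect["colMin"] < 2L) {
    message("region ", id, " has texture support smaller than 3 x 3; dropped")
    return(NULL)
  }
  gray <- hsi@intensity[rect["rowMin"]:rect["rowMax"],
                        rect["colMin"]:rect["colMax"], drop = FALSE]
  out <- c(colorFeatures(img, mask, hsi = hsi, lab = lab),
           glcmFeatures(gray, k = k),
           lbpHistogram(gray))
  names(out) <- featureNames78()
  out
}

#' Descriptors for every region of a RegionSet
#'
#' Applies [regionFeatureVector()] to each region, silently dropping (and
#' recording) regions whose texture support is degenerate.
#'
#' @inheritParams regionFeatureVector
#' @param labels optional factor/character of per-region labels
#'   (`tree`/`background`).
#' @return a [RegionFeatures-class]; dropped region ids are in
#'   `meta` attribute `droppedIds`.
#' @export
regionFeatures <- function(img, rs, mode = c("inner_rect", "full_mask"),
                           labels = NULL, k = 16L) {
  mode <- match.arg(mode)
  hsi <- rgbToHsi(img)
  lab <- rgbToLab(img)
  ids <- regionTable(rs)$id
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows[[i]] <- suppressMessages(
      regionFeatureVector(img, rs, ids[i], mode, hsi = hsi, lab = lab, k = k))
  }
  keep <- !vapply(rows, is.null, logical(1))
  feat <- do.call(rbind, rows[keep])
  if (is.null(feat)) feat <- matrix(numeric(), 0L, 78L,
                                    dimnames = list(NULL, featureNames78()))
  labs <- if (is.null(labels)) {
    factor(rep(NA_character_, sum(keep)), levels = c("background", "tree"))
  } else {
    factor(as.character(labels)[keep], levels = c("background", "tree"))
  }
  res <- new("RegionFeatures", features = feat, labels = labs,
             regionIds = as.integer(ids[keep]))
  attr(res@features, "droppedIds") <- ids[!keep]
  res
}

#' Write a feature table to CSV
#'
#' Fixed, documented column order: `regionId`, `label`, then the 78 feature
#' columns of [featureNames78()].
#'
#' @param rf a [RegionFeatures-class].
#' @param path output file.
#' @export
writeFeatureCsv <- function(rf, path) {
  stopifnot(is(rf, "RegionFeatures"))
  df <- data.frame(regionId = rf@regionIds,
                   label = as.character(rf@labels),
                   rf@features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
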