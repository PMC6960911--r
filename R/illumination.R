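#' @include color.R
NULL

#' Green-hue selection mask
#'
#' Pixels whose hue falls in the green band (default `[pi/2, pi]`, inclusive)
#' form the putative vegetation foreground S_g used for selective illumination
#' compensation and for the scene's green-cover ratio A.
#'
#' @param hsi an [HSIImage-class].
#' @param hueRange inclusive hue bounds in radians.
#' @return logical matrix (TRUE = selected).
#' @export
greenSelectionMask <- function(hsi, hueRange = c(pi / 2, pi)) {
  stopifnot(is(hsi, "HSIImage"), length(hueRange) == 2L)
  hsi@hue >= hueRange[1L] & hsi@hue <= hueRange[2L]
}

# 256-level cumulative-histogram equalization of values in [0, 1], kept
# continuous (no requantization). The transfer is scaled to (L-1)/L, the
# classic discrete-HE output range: the brightest occupied bin maps to
# 255/256, not 1.0, so a compensated pixel never saturates to pure white and
# its hue stays defined. Monotone; a single-level input is returned
# unchanged.
histEqualize <- function(v, bins = 256L) {
  bins <- as.integer(bins)
  # the 1e-9 guard keeps a tied group together when an equalized value sits
  # exactly on a bin edge and round-trip noise straddles it
  idx <- pmin(floor(v * bins + 1e-9), bins - 1L) + 1L
  counts <- tabulate(idx, nbins = bins)
  if (sum(counts > 0L) <= 1L) return(v)
  cdf <- cumsum(counts) / length(v) * (bins - 1L) / bins
  cdf[idx]
}

#' Selective illumination compensation (green-region equalization)
#'
#' Equalizes the intensity histogram restricted to green-hue pixels, leaving
#' hue, saturation and all non-green pixels untouched, then converts back to
#' RGB. This lifts the brightness contrast of under-lit canopies without the
#' background dominating the transfer function, unlike [globalHe()]. Images
#' with no green pixels pass through unchanged. Pixels pushed out of gamut by
#' the compensation are desaturated just enough to fit (hue and compensated
#' intensity stay exact; see [hsiToRgb()]), which keeps the equalization
#' idempotent.
#'
#' @param img an [RGBImage-class].
#' @param hueRange green hue band (radians).
#' @param bins equalization bin count.
#' @return an [RGBImage-class].
#' @export
srihe <- function(img, hueRange = c(pi / 2, pi), bins = 256L) {
  stopifnot(is(img, "RGBImage"))
  hsi <- rgbToHsi(img)
  sg <- greenSelectionMask(hsi, hueRange)
  if (!any(sg)) return(img)
  I2 <- hsi@intensity
  I2[sg] <- histEqualize(I2[sg], bins)
  hsiToRgb(new("HSIImage", hue = hsi@hue, sat = hsi@sat, intensity = I2),
           gamut = "desaturate")
}

#' Global intensity histogram equalization (baseline)
#'
#' Standard whole-image equalization of the HSI intensity plane; the baseline
#' against which the selective variant is compared. A constant intensity
#' plane is returned unchanged.
#'
#' @inheritParams srihe
#' @return an [RGBImage-class].
#' @export
globalHe <- function(img, bins = 256L) {
  stopifnot(is(img, "RGBImage"))
  hsi <- rgbToHsi(img)
  I2 <- matrix(histEqualize(as.vector(hsi@intensity), bins),
               nrow(hsi@intensity), ncol(hsi@intensity))
  hsiToRgb(new("HSIImage", hue = hsi@hue, sat = hsi@sat, intensity = I2),
           gamut = "desaturate")
}

#' Classify the scene brightness condition
#'
#' The mean intensity I_A over the green-hue foreground decides between
#' insufficient brightness (`IB`, I_A < 0.3) and sufficient brightness (`SB`,
#' I_A >= 0.3). An image with no green pixels is classified `SB` with a
#' warning.
#'
#' @param img an [RGBImage-class].
#' @param threshold decision boundary on I_A (default 0.3; the boundary value
#'   itself maps to `SB`).
#' @param hueRange green hue band (radians).
#' @return `"IB"` or `"SB"`, with the attribute `meanForegroundI`.
#' @export
classifyBrightness <- function(img, threshold = 0.3, hueRange = c(pi / 2, pi)) {
  stopifnot(is(img, "RGBImage"))
  hsi <- rgbToHsi(img)
  sg <- greenSelectionMask(hsi, hueRange)
  if (!any(sg)) {
    warning("no green-hue pixels; brightness condition defaults to SB")
    return(structure("SB", meanForegroundI = NA_real_))
  }
  ia <- mean(hsi@intensity[sg])
  structure(if (ia < threshold) "IB" else "SB", meanForegroundI = ia)
}
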