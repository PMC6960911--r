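#' @include color.R threshold.R regions.R
NULL

#' Under-extraction judgement rule
#'
#' Primary extraction on weedy scenes fuses crowns and weeds: the foreground
#' area ratio A rises sharply while the number of separate regions N
#' collapses. The rule flags a result as under-extracted when `A(%) > tA` or
#' `N < tN`. The defaults (tA = 45, tN = 20) sit one standard deviation
#' beyond the true per-frame crown statistics of orchard imagery at this
#' working scale (true A about 34 +/- 11.5%, true N about 28 +/- 7.7 trees).
#'
#' @param regions a [RegionSet-class] from [extractRoisErgcm()].
#' @param tA area-ratio threshold in percent.
#' @param tN region-count threshold.
#' @return `TRUE` if the result is judged under-extracted.
#' @export
uejrIsUnderExtracted <- function(regions, tA = 45, tN = 20L) {
  stopifnot(is(regions, "RegionSet"))
  100 * areaFraction(regions) > tA || regionCount(regions) < tN
}

#' Multi-scale retinex reflectance
#'
#' Per channel i and Gaussian surround scale j:
#' `R_i = sum_j W_j (log(S_i + eps) - log(S_i * G_j + eps))`, and
#' `M_i = exp(R_i)` (`*` = convolution, kernels unit-sum, reflected borders).
#' M is the scene reflectance freed of smooth illumination: a global
#' multiplicative brightness change cancels in the log difference, and
#' compact chromatic anomalies (crowns against an extended background) stand
#' out against their large-scale surround.
#'
#' @param img an [RGBImage-class].
#' @param sigmas the three surround scales in px (default `c(15, 80, 250)`,
#'   the conventional small/medium/large retinex triple).
#' @param weights per-scale weights summing to 1.
#' @param epsilon log-guard constant.
#' @return an `H x W x 3` numeric array of reflectance values (values near 1
#'   mean "at local average"; not an [RGBImage-class], as reflectance is not
#'   bounded by 1).
#' @export
msrReflectance <- function(img, sigmas = c(15, 80, 250),
                           weights = rep(1 / 3, 3), epsilon = 1e-6) {
  stopifnot(is(img, "RGBImage"), length(sigmas) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  d <- img@data
  out <- array(0, dim(d))
  for (i in 1:3) {
    S <- chPlane(d, i)
    logS <- log(S + epsilon)
    R <- 0
    for (j in seq_along(sigmas)) {
      blur <- gaussianBlur(S, sigmas[j])
      R <- R + weights[j] * (logS - log(pmax(blur, 0) + epsilon))
    }
    out[, , i] <- exp(R)
  }
  out
}

#' Excess-green chromatic map 2G - R - B
#'
#' Per pixel, `2G - R - B` — the superposition of the G-R and G-B
#' aberrations — typically computed on a retinex reflectance image, where it
#' isolates compact green anomalies from an extended weedy background.
#'
#' @param x an [RGBImage-class] or an `H x W x 3` numeric array (e.g. the
#'   output of [msrReflectance()]).
#' @return a [ChromaticMap-class] of kind `"twoG_R_B"`.
#' @export
chromatic2grb <- function(x) {
  d <- if (is(x, "RGBImage")) x@data else x
  if (length(dim(d)) != 3L || dim(d)[3L] != 3L)
    stop("input must be an H x W x 3 array or RGBImage")
  new("ChromaticMap",
      data = 2 * chPlane(d, 2L) - chPlane(d, 1L) - chPlane(d, 3L),
      kind = "twoG_R_B")
}

#' Re-extraction chain for under-extracted scenes (retinex + 2G-R-B)
#'
#' For scenes where the primary chain fused crowns with weeds:
#' (1) [msrReflectance()]; (2) [chromatic2grb()] on the reflectance;
#' (3) grayscale closing (disk `closingRadius`) to solidify crown texture
#' into per-crown bright domes; (4) white top-hat (disk `tophatRadius`) to
#' delete the slowly varying weed/soil background, keeping the compact crown
#' caps; (5) Otsu binarization of the top-hat map (foreground above
#' threshold); (6) per-component convex-hull filling, recovering crown edges
#' eaten by the large-radius morphology; (7) removal of components smaller
#' than `minAreaFrac` of the image area. An additional grayscale opening of
#' the top-hat map before binarization is available via `openingRadius`; it
#' is off by default because at radii comparable to `tophatRadius` it
#' suppresses the crown caps themselves (see the methods vignette).
#'
#' @param img an [RGBImage-class].
#' @param sigmas,weights,epsilon retinex parameters, see [msrReflectance()].
#' @param closingRadius,tophatRadius disk radii in px (defaults 20, 24).
#' @param openingRadius optional pre-threshold opening radius (default 0 =
#'   off).
#' @param minAreaFrac minimum kept region area as a fraction of image area.
#' @return a [RegionSet-class]; components are convex. A degenerate
#'   (constant) filtered map yields an empty set with a warning.
#' @export
extractRoisEmsrcm <- function(img, sigmas = c(15, 80, 250),
                              weights = rep(1 / 3, 3), epsilon = 1e-6,
                              closingRadius = 20L, tophatRadius = 24L,
                              openingRadius = 0L, minAreaFrac = 5e-4) {
  stopifnot(is(img, "RGBImage"))
  M <- msrReflectance(img, sigmas, weights, epsilon)
  g <- chromatic2grb(M)@data
  # min-max normalize: grayscale morphology commutes with affine rescaling
  # (and EBImage expects [0,1]); the Otsu split is likewise scale-free
  rngG <- range(g)
  if (rngG[2L] - rngG[1L] > 0) g <- (g - rngG[1L]) / (rngG[2L] - rngG[1L])
  g <- EBImage::closing(asImage(g), discBrush(closingRadius))
  g <- EBImage::whiteTopHat(g, discBrush(tophatRadius))
  if (openingRadius > 0)
    g <- EBImage::opening(g, discBrush(openingRadius))
  g <- as.matrix(EBImage::imageData(g))
  thr <- tryCatch(otsuThreshold(g), error = function(e) NULL)
  if (is.null(thr)) {
    warning("degenerate filtered map; returning empty region set")
    return(emptyRegionSet(dim(g)))
  }
  mask <- g > thr
  mask <- convexHullFill(mask)
  filterSmallRegions(labelRegions(mask), minAreaFrac)
}
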