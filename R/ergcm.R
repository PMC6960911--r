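#' @include color.R threshold.R regions.R
NULL

#' Brightness-relative G-R chromatic map
#'
#' Per pixel, `(G - R) / I` with `I = (R + G + B) / 3`, and 0 where `I = 0`.
#' Dividing the green-red aberration by the pixel brightness removes the
#' dependence on local illumination: scaling a pixel's RGB by any positive
#' constant leaves the index unchanged, so shaded and sunlit canopy score
#' alike.
#'
#' @param img an [RGBImage-class] (in the full pipeline, after [srihe()]).
#' @return a [ChromaticMap-class] of kind `"relative_gr"`.
#' @export
relativeGRMap <- function(img) {
  stopifnot(is(img, "RGBImage"))
  d <- img@data
  I <- (chPlane(d, 1L) + chPlane(d, 2L) + chPlane(d, 3L)) / 3
  m <- ifelse(I > 0, (chPlane(d, 2L) - chPlane(d, 1L)) / ifelse(I > 0, I, 1), 0)
  new("ChromaticMap", data = m, kind = "relative_gr")
}

#' Primary region extraction (relative G-R chromatic map)
#'
#' The primary extraction chain: (1) [relativeGRMap()]; (2) Otsu threshold,
#' keeping pixels above it; (3) removal of components smaller than
#' `minAreaFrac` of the image area (green specks such as isolated weeds);
#' (4) morphological closing with a disk to smooth jagged boundaries;
#' (5) hole filling. Precise on scenes with little weed cover, but weedy
#' backgrounds score high on the same index and merge into the foreground —
#' the under-extraction rule ([uejrIsUnderExtracted()]) detects that and
#' hands over to [extractRoisEmsrcm()].
#'
#' @param img an [RGBImage-class].
#' @param minAreaFrac minimum region area as a fraction of image area
#'   (default 0.0005, i.e. 0.05%; the smallest real crown covers about 0.1%).
#' @param diskRadius closing disk radius in px (default 5).
#' @return a [RegionSet-class]. A constant chromatic map yields an empty set
#'   with a warning.
#' @export
extractRoisErgcm <- function(img, minAreaFrac = 5e-4, diskRadius = 5L) {
  stopifnot(is(img, "RGBImage"))
  cm <- relativeGRMap(img)
  thr <- tryCatch(otsuThreshold(cm), error = function(e) NULL)
  if (is.null(thr)) {
    warning("degenerate chromatic map; returning empty region set")
    return(emptyRegionSet(dim(cm@data)))
  }
  mask <- cm@data > thr
  rs <- filterSmallRegions(labelRegions(mask), minAreaFrac)
  mask <- rs@labelMap > 0L
  if (diskRadius > 0) {
    mask <- EBImage::closing(asImage(mask * 1), discBrush(diskRadius)) > 0.5
  }
  mask <- EBImage::fillHull(asImage(mask * 1)) > 0.5
  labelRegions(mask)
}
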