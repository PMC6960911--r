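#' @include AllClasses.R utils.R
NULL

#' Read / write RGB images
#'
#' Thin wrappers around EBImage's readers (JPEG/PNG/TIFF), converting between
#' EBImage's (x, y, channel) layout and this package's row-major
#' `H x W x 3` convention. Grayscale files are replicated to three channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @param img an [RGBImage-class].
#' @return `readRGBImage` an [RGBImage-class]; writers return the path,
#'   invisibly.
#' @export
readRGBImage <- function(path) {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3L] > 3L) d <- d[, , 1:3, drop = FALSE]
  RGBImage(clip01(aperm(d, c(2L, 1L, 3L))))
}

#' @rdname readRGBImage
#' @export
writeRGBImage <- function(img, path) {
  stopifnot(is(img, "RGBImage"))
  d <- aperm(img@data, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(d, colormode = "Color"), path)
  invisible(path)
}

#' Read / write binary masks and label maps as 8-bit PNG
#'
#' Masks are written with background 0 and foreground 255; label maps store
#' the region id directly in the 8-bit gray value (ids above 255 are not
#' supported — scenes here carry a few dozen trees).
#'
#' @param mask logical matrix.
#' @param labelMap integer matrix (0 = background).
#' @param path PNG path.
#' @return readers return the matrix; writers the path, invisibly.
#' @export
writeMaskPng <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  d <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  t(d) > 0.5
}

#' @rdname writeMaskPng
#' @export
writeLabelPng <- function(labelMap, path) {
  if (max(labelMap) > 255L) stop("label maps above 255 ids are not supported")
  EBImage::writeImage(EBImage::Image(t(labelMap / 255)), path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readLabelPng <- function(path) {
  d <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  m <- t(d)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
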