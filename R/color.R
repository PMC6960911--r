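#' @include AllClasses.R utils.R
NULL

#' Convert RGB to HSI
#'
#' Converts an in-gamut RGB image to hue/saturation/intensity with hue in
#' `[0, 2*pi]`. Intensity is the arithmetic mean `(R + G + B) / 3`, chosen so
#' that brightness-relative chromatic indices scale linearly with the RGB
#' values. Saturation is `1 - 3 * min(R, G, B) / (R + G + B)` for positive
#' intensity and 0 otherwise. Hue uses the standard arccos form, reflected to
#' `[pi, 2*pi]` where `B > G`; achromatic pixels take hue 0 and saturation 0.
#'
#' @param img an [RGBImage-class].
#' @return an [HSIImage-class].
#' @seealso [hsiToRgb()] for the inverse.
#' @examples
#' px <- RGBImage(array(c(0, 1, 0), c(1, 1, 3)))
#' hsi <- rgbToHsi(px)   # pure green: H = 2*pi/3, S = 1, I = 1/3
#' @export
rgbToHsi <- function(img) {
  stopifnot(is(img, "RGBImage"))
  d <- img@data
  R <- chPlane(d, 1L); G <- chPlane(d, 2L); B <- chPlane(d, 3L)
  I <- (R + G + B) / 3
  tot <- R + G + B
  minc <- pmin(R, G, B)
  S <- ifelse(tot > 0, 1 - 3 * minc / tot, 0)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  achrom <- den < .Machine$double.eps
  ratio <- ifelse(achrom, 1, num / pmax(den, .Machine$double.eps))
  theta <- acos(pmin(pmax(ratio, -1), 1))
  H <- ifelse(B > G, 2 * pi - theta, theta)
  H[achrom] <- 0
  S[achrom & tot > 0] <- 0   # R = G = B: saturation 0 by convention
  S <- clip01(S)
  new("HSIImage", hue = H, sat = S, intensity = I)
}

#' Convert HSI to RGB
#'
#' Inverse of [rgbToHsi()] via the standard three-sector formula.
#' Round-tripping an in-gamut image reproduces it to within 1e-6. Synthesized
#' HSI triplets can exceed the RGB gamut (a bright, saturated intensity has
#' `max(R,G,B) = I(1+2S) > 1`); `gamut` picks the policy: `"clip"` truncates
#' channels to `[0, 1]` (hue/saturation distort on affected pixels), while
#' `"desaturate"` compresses the pixel's saturation just enough to fit,
#' keeping hue and intensity exact — the policy the illumination equalizers
#' use so that a pixel's compensated intensity survives the conversion.
#'
#' @param hsi an [HSIImage-class].
#' @param gamut `"clip"` (default) or `"desaturate"`.
#' @return an [RGBImage-class].
#' @export
hsiToRgb <- function(hsi, gamut = c("clip", "desaturate")) {
  stopifnot(is(hsi, "HSIImage"))
  gamut <- match.arg(gamut)
  H <- hsi@hue; S <- hsi@sat; I <- hsi@intensity
  H <- H %% (2 * pi)
  R <- G <- B <- I * 0
  sector <- findInterval(H, c(0, 2 * pi / 3, 4 * pi / 3), rightmost.closed = FALSE)
  h0 <- H - (sector - 1L) * 2 * pi / 3
  # within-sector channel triplet (lead, mid, trail):
  lead <- I * (1 - S)
  mid  <- I * (1 + S * cos(h0) / cos(pi / 3 - h0))
  s1 <- sector == 1L; s2 <- sector == 2L; s3 <- sector == 3L
  B[s1] <- lead[s1]; R[s1] <- mid[s1]; G[s1] <- (3 * I - R - B)[s1]
  R[s2] <- lead[s2]; G[s2] <- mid[s2]; B[s2] <- (3 * I - R - G)[s2]
  G[s3] <- lead[s3]; B[s3] <- mid[s3]; R[s3] <- (3 * I - G - B)[s3]
  if (gamut == "desaturate") {
    # channels are affine in S about I, and only the upper bound can be
    # exceeded: shrink towards I where max(R,G,B) > 1
    mx <- pmax(R, G, B)
    f <- ifelse(mx > 1, (1 - I) / pmax(mx - I, .Machine$double.eps), 1)
    R <- I + f * (R - I); G <- I + f * (G - I); B <- I + f * (B - I)
  }
  out <- array(0, c(dim(I), 3L))
  out[, , 1L] <- R; out[, , 2L] <- G; out[, , 3L] <- B
  RGBImage(clip01(out))
}

#' Convert RGB to CIE L*a*b* (D65)
#'
#' Standard sRGB -> XYZ (D65) -> L*a*b*, delegated to
#' [grDevices::convertColor()].
#'
#' @param img an [RGBImage-class]; sRGB encoding assumed.
#' @return a [LabImage-class].
#' @export
rgbToLab <- function(img) {
  stopifnot(is(img, "RGBImage"))
  d <- img@data
  dm <- dim(d)[1:2]
  m <- cbind(as.vector(d[, , 1L]), as.vector(d[, , 2L]), as.vector(d[, , 3L]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  new("LabImage",
      L = matrix(lab[, 1L], dm[1L], dm[2L]),
      a = matrix(lab[, 2L], dm[1L], dm[2L]),
      b = matrix(lab[, 3L], dm[1L], dm[2L]))
}
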