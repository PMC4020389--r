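#' sRGB to CIE 1976 (L*, a*, b*) conversion
#'
#' Converts 8-bit sRGB to CIELAB under the standard sRGB transfer function
#' (IEC 61966-2-1) and the D65 reference white. The white point is taken as
#' the image of RGB = (1, 1, 1) under the sRGB primaries matrix, so the
#' neutral axis maps exactly to `a* = b* = 0` and white to `L* = 100`.
#'
#' @param image an [rgb_raster] (8-bit values in `[0, 255]`).
#' @return a [lab_raster] of the same dimensions.
#' @export
srgb_to_lab <- function(image) {
  if (!inherits(image, "rgb_raster")) image <- rgb_raster(image)
  d <- dim(image)
  rgb <- matrix(unclass(image), ncol = 3L) / 255
  lab <- srgb_to_lab_rows(rgb)
  out <- array(lab, dim = d)
  lab_raster(out)
}

#' CIE Lab to sRGB conversion
#'
#' Inverse of [srgb_to_lab()], used mainly to render synthetic fixtures.
#' Out-of-gamut channel values are clipped to `[0, 255]`; the number of
#' clipped pixels is attached as attribute `n_clipped`.
#'
#' @param image a [lab_raster].
#' @return an [rgb_raster] with attribute `n_clipped`.
#' @export
lab_to_srgb <- function(image) {
  if (!inherits(image, "lab_raster")) image <- lab_raster(image)
  d <- dim(image)
  lab <- matrix(unclass(image), ncol = 3L)
  rgb <- lab_to_srgb_rows(lab)
  n_clip <- sum(rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) > 0)
  rgb <- pmin(pmax(rgb, 0), 1)
  out <- rgb_raster(array(round(rgb * 255), dim = d))
  attr(out, "n_clipped") <- n_clip
  out
}

# sRGB (IEC 61966-2-1) linear-RGB -> XYZ matrix, D65
.srgb_M <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505
), nrow = 3, byrow = TRUE)

# White = image of (1,1,1): row sums, so equal-RGB input is exactly neutral.
.srgb_white <- rowSums(.srgb_M)

srgb_to_lab_rows <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_M)
  r <- sweep(xyz, 2, .srgb_white, "/")
  f <- lab_f(r)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

lab_to_srgb_rows <- function(lab) {
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  r <- cbind(lab_f_inv(fx), lab_f_inv(fy), lab_f_inv(fz))
  xyz <- sweep(r, 2, .srgb_white, "*")
  lin <- xyz %*% t(solve(.srgb_M))
  ifelse(lin <= 0.04045 / 12.92, lin * 12.92, 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
}

# CIE f(): cube root above (6/29)^3, linear segment below
lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert single Lab triples to 8-bit sRGB triples
#'
#' Vectorised helper over rows of a 3-column matrix; used by the phantom
#' renderer and by tests.
#'
#' @param lab numeric matrix with columns L, a, b (or a length-3 vector).
#' @return numeric matrix of sRGB values in `[0, 255]` (unclipped count lost).
#' @export
lab_triples_to_srgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  rgb <- lab_to_srgb_rows(lab)
  round(pmin(pmax(rgb, 0), 1) * 255)
}

#' @rdname lab_triples_to_srgb
#' @param rgb numeric matrix of 8-bit sRGB values.
#' @export
srgb_triples_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  srgb_to_lab_rows(rgb / 255)
}
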