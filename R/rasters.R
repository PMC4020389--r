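#' Raster containers
#'
#' Images are stored as plain numeric arrays with a light S3 class on top.
#' An `rgb_raster` is a `height x width x 3` array of 8-bit intensities in
#' `[0, 255]`; a `lab_raster` is a `height x width x 3` array holding the CIE
#' 1976 `L*` (lightness, 0-100), `a*` (red-green) and `b*` (yellow-blue)
#' coordinates. A `tongue_mask` is a logical `height x width` matrix with a
#' `provenance` attribute (`"auto"`, `"manual"` or `"merged"`).
#'
#' @param x numeric array (`h x w x 3`) for rasters; logical matrix for masks.
#' @param provenance one of `"auto"`, `"manual"`, `"merged"`.
#' @return An object of the corresponding class.
#' @name rasters
NULL

#' @rdname rasters
#' @export
rgb_raster <- function(x) {
  x <- as_channel_array(x, "rgb_raster")
  if (min(x) < 0 || max(x) > 255)
    stop("rgb_raster channel values must lie in [0, 255]", call. = FALSE)
  structure(x, class = c("rgb_raster", "array"))
}

#' @rdname rasters
#' @export
lab_raster <- function(x) {
  x <- as_channel_array(x, "lab_raster")
  if (!all(is.finite(x)))
    stop("lab_raster values must be finite", call. = FALSE)
  L <- x[, , 1]
  if (min(L) < -1e-9 || max(L) > 100 + 1e-9)
    stop("lab_raster L* values must lie in [0, 100]", call. = FALSE)
  dimnames(x) <- list(NULL, NULL, c("L", "a", "b"))
  structure(x, class = c("lab_raster", "array"))
}

#' @rdname rasters
#' @export
tongue_mask <- function(x, provenance = "auto") {
  if (!is.matrix(x)) stop("mask must be a matrix", call. = FALSE)
  provenance <- match.arg(provenance, c("auto", "manual", "merged"))
  structure(matrix(as.logical(x), nrow(x), ncol(x)),
            provenance = provenance, class = c("tongue_mask", "matrix"))
}

as_channel_array <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3-d array (height x width x channels)", call. = FALSE)
  if (dim(x)[3] != 3L)
    stop(what, " must have exactly 3 channels, got ", dim(x)[3], call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop(what, " must be at least 1 x 1", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Read an 8-bit RGB image
#'
#' Supports PNG and TIFF. Alpha channels and non-3-channel images are rejected.
#'
#' @param path file path; format inferred from the extension.
#' @return an [rgb_raster] with values in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = stop("JPEG input is not supported by this build; convert to PNG or TIFF",
                call. = FALSE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L)
    stop("grayscale image: 3-channel RGB required", call. = FALSE)
  if (dim(img)[3] == 4L)
    stop("image has an alpha channel; flatten to 3-channel RGB first", call. = FALSE)
  if (dim(img)[3] != 3L)
    stop("expected 3 channels, got ", dim(img)[3], call. = FALSE)
  rgb_raster(round(img * 255))
}

#' Write an 8-bit RGB image as PNG
#'
#' @param image an [rgb_raster].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_raster"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Read / write binary masks as single-channel PNG
#'
#' Convention: 0 = background, anything above 127 of 255 = tongue.
#'
#' @param path file path.
#' @param provenance provenance recorded on the mask read in.
#' @return [read_mask()]: a [tongue_mask]; [write_mask()]: `path` invisibly.
#' @export
read_mask <- function(path, provenance = "manual") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  tongue_mask(img > 0.5, provenance = provenance)
}

#' @rdname read_mask
#' @param mask a [tongue_mask] or logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @export
print.rgb_raster <- function(x, ...) {
  cat(sprintf("<rgb_raster %d x %d, range [%g, %g]>\n",
              dim(x)[1], dim(x)[2], min(x), max(x)))
  invisible(x)
}

#' @export
print.lab_raster <- function(x, ...) {
  cat(sprintf("<lab_raster %d x %d, L* [%.1f, %.1f], a* [%.1f, %.1f], b* [%.1f, %.1f]>\n",
              dim(x)[1], dim(x)[2], min(x[, , 1]), max(x[, , 1]),
              min(x[, , 2]), max(x[, , 2]), min(x[, , 3]), max(x[, , 3])))
  invisible(x)
}

#' @export
print.tongue_mask <- function(x, ...) {
  cat(sprintf("<tongue_mask %d x %d, %d tongue pixels, provenance=%s>\n",
              nrow(x), ncol(x), sum(x), attr(x, "provenance")))
  invisible(x)
}

#' Convert a Lab raster to a tidy tibble
#'
#' One row per pixel with `row`, `col`, `L`, `a`, `b` columns; handy for
#' ggplot2 and dplyr work on small images.
#'
#' @param x a [lab_raster].
#' @param ... unused.
#' @return a tibble with one row per pixel.
#' @exportS3Method generics::tidy
tidy.lab_raster <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    L = as.vector(x[, , 1]),
    a = as.vector(x[, , 2]),
    b = as.vector(x[, , 3])
  )
}

#' Dice overlap coefficient between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical matrices of equal dimensions.
#' @return a scalar in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ", call. = FALSE)
  2 * sum(a & b) / (sum(a) + sum(b))
}
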