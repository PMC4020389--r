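#' Exclusion thresholds
#'
#' Dark tongue-root pixels (low illumination) and specular highlights
#' (saliva reflections) are removed from the tongue mask by thresholding on
#' `L*`: pixels strictly below the dark threshold or strictly above the
#' bright threshold are excluded; pixels exactly at a threshold are retained.
#'
#' @param dark_threshold `L*` below which pixels are excluded (default 30).
#' @param bright_threshold `L*` above which pixels are excluded (default 85).
#' @return a validated parameter list.
#' @export
exclusion_params <- function(dark_threshold = 30, bright_threshold = 85) {
  if (!(dark_threshold >= 0 && dark_threshold < bright_threshold &&
        bright_threshold <= 100))
    stop("need 0 <= dark_threshold < bright_threshold <= 100", call. = FALSE)
  list(dark_threshold = dark_threshold, bright_threshold = bright_threshold)
}

#' Valid-pixel mask after dark/specular exclusion
#'
#' Retains tongue pixels with `dark_threshold <= L* <= bright_threshold`.
#' Removal counts per cause are attached as attribute `exclusion_report`
#' (also containing fractions of the tongue mask).
#'
#' @param lab a [lab_raster].
#' @param tongue a [tongue_mask] of matching dimensions.
#' @param params an [exclusion_params()] list.
#' @return a [tongue_mask] of valid pixels with attribute `exclusion_report`.
#' @export
valid_pixel_mask <- function(lab, tongue, params = exclusion_params()) {
  stopifnot(inherits(lab, "lab_raster"))
  d <- dim(lab)
  L <- matrix(unclass(lab)[, , 1], d[1], d[2])
  if (!all(dim(tongue) == d[1:2]))
    stop("mask dimensions do not match the image", call. = FALSE)
  params <- exclusion_params(params$dark_threshold, params$bright_threshold)
  tm <- unclass(tongue)
  dark <- tm & (L < params$dark_threshold)
  bright <- tm & (L > params$bright_threshold)
  valid <- tm & !dark & !bright
  n <- sum(tm)
  report <- list(
    n_tongue = n,
    n_removed_dark = sum(dark),
    n_removed_bright = sum(bright),
    n_retained = sum(valid),
    frac_removed_dark = if (n > 0) sum(dark) / n else NA_real_,
    frac_removed_bright = if (n > 0) sum(bright) / n else NA_real_
  )
  out <- tongue_mask(valid, provenance = attr(tongue, "provenance"))
  attr(out, "exclusion_report") <- report
  out
}
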