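#' Default synthetic checker reference values
#'
#' A 12-patch layout: 6 achromatic patches (neutral grays, `L*` from 20 to
#' 95, used to fit the `L*` correction) and 6 chromatic patches (saturated
#' in-gamut colours spanning the `a*` and `b*` axes, used to fit the `a*`
#' and `b*` corrections). Commercial checkers ship their own reference
#' values; supply them through this same table when available.
#'
#' @return a tibble with columns `patch_id`, `role`, `L_ref`, `a_ref`,
#'   `b_ref`.
#' @export
checker_reference <- function() {
  tibble::tibble(
    patch_id = paste0(rep(c("A", "C"), each = 6), rep(1:6, 2)),
    role = rep(c("achromatic", "chromatic"), each = 6),
    L_ref = c(20, 35, 50, 65, 80, 95,
              50.2, 65.7, 51.0, 67.5, 45.3, 64.1),
    a_ref = c(rep(0, 6),
              47.8, -49.5, 10.6, 18.4, 41.8, -28.6),
    b_ref = c(rep(0, 6),
              24.9, 41.8, -45.9, 55.9, -31.2, -8.7)
  )
}

#' Sample checker patches from an image
#'
#' Measures each patch as the mean Lab triple over a rectangular region.
#'
#' @param lab a [lab_raster].
#' @param patch_regions a data frame with columns `patch_id`, `row0`, `row1`,
#'   `col0`, `col1` (1-based inclusive bounds) for the 12 patches.
#' @param reference a reference table as from [checker_reference()].
#' @return a `checker_set`: tibble with reference and measured Lab columns.
#' @export
sample_checker <- function(lab, patch_regions, reference = checker_reference()) {
  stopifnot(inherits(lab, "lab_raster"))
  arr <- unclass(lab)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (nrow(patch_regions) != 12L)
    stop("expected 12 patch regions, got ", nrow(patch_regions), call. = FALSE)
  meas <- purrr::pmap_dfr(patch_regions, function(patch_id, row0, row1, col0, col1, ...) {
    if (row0 < 1 || col0 < 1 || row1 > h || col1 > w)
      stop("patch region '", patch_id, "' lies outside the image", call. = FALSE)
    if ((row1 - row0 + 1) * (col1 - col0 + 1) < 4)
      stop("patch region '", patch_id, "' is smaller than 4 px", call. = FALSE)
    tibble::tibble(
      patch_id = patch_id,
      L_meas = mean(arr[row0:row1, col0:col1, 1]),
      a_meas = mean(arr[row0:row1, col0:col1, 2]),
      b_meas = mean(arr[row0:row1, col0:col1, 3])
    )
  })
  out <- dplyr::inner_join(reference, meas, by = "patch_id")
  if (nrow(out) != 12L)
    stop("patch ids do not match the reference table", call. = FALSE)
  if (sum(out$role == "achromatic") != 6L || sum(out$role == "chromatic") != 6L)
    stop("checker must contain exactly 6 achromatic and 6 chromatic patches",
         call. = FALSE)
  class(out) <- c("checker_set", class(out))
  out
}

#' Build a checker set directly from measured values
#'
#' Convenience for simulation and testing, bypassing image sampling.
#'
#' @param measured matrix/data frame with 12 rows and columns `L_meas`,
#'   `a_meas`, `b_meas` in the row order of `reference`.
#' @param reference reference table as from [checker_reference()].
#' @return a `checker_set` tibble.
#' @export
checker_set <- function(measured, reference = checker_reference()) {
  measured <- as.data.frame(measured)
  stopifnot(nrow(measured) == 12L)
  out <- dplyr::bind_cols(reference, tibble::as_tibble(measured))
  if (!all(is.finite(as.matrix(measured))))
    stop("measured checker values must be finite", call. = FALSE)
  class(out) <- c("checker_set", class(out))
  out
}

#' Fit the per-coordinate linear colour correction
#'
#' Ordinary least squares of reference on measured, one affine map per Lab
#' coordinate: the `L*` map is fitted on the 6 achromatic patches, the `a*`
#' and `b*` maps on the 6 chromatic patches. An optional cross-channel mode
#' fits a full affine 3x3 map on all 12 patches instead.
#'
#' @param checker a `checker_set` from [sample_checker()] or [checker_set()].
#' @param mode `"per_coordinate"` (default) or `"cross_channel"`.
#' @return a `correction_model` with slopes/intercepts and residual sums of
#'   squares per coordinate.
#' @export
fit_correction <- function(checker, mode = c("per_coordinate", "cross_channel")) {
  mode <- match.arg(mode)
  achro <- checker[checker$role == "achromatic", ]
  chrom <- checker[checker$role == "chromatic", ]
  fit1 <- function(x, y, coord) {
    if (length(unique(x)) < 2)
      stop("degenerate checker: all measured ", coord, " values equal", call. = FALSE)
    co <- stats::coef(stats::lm(y ~ x))
    rss <- sum((y - (co[1] + co[2] * x))^2)
    list(slope = unname(co[2]), intercept = unname(co[1]), rss = rss)
  }
  if (mode == "per_coordinate") {
    fl <- fit1(achro$L_meas, achro$L_ref, "L*")
    fa <- fit1(chrom$a_meas, chrom$a_ref, "a*")
    fb <- fit1(chrom$b_meas, chrom$b_ref, "b*")
    if (any(c(fl$slope, fa$slope, fb$slope) <= 0))
      warning("non-positive correction slope: physically implausible fit",
              call. = FALSE)
    model <- list(
      mode = mode,
      coefficients = tibble::tibble(
        coordinate = c("L", "a", "b"),
        slope = c(fl$slope, fa$slope, fb$slope),
        intercept = c(fl$intercept, fa$intercept, fb$intercept),
        rss = c(fl$rss, fa$rss, fb$rss),
        n_patches = c(6L, 6L, 6L)
      )
    )
  } else {
    X <- as.matrix(checker[, c("L_meas", "a_meas", "b_meas")])
    Y <- as.matrix(checker[, c("L_ref", "a_ref", "b_ref")])
    fit <- stats::lm(Y ~ X)
    model <- list(
      mode = mode,
      matrix = t(stats::coef(fit)[-1, , drop = FALSE]),
      offset = as.vector(stats::coef(fit)[1, ]),
      coefficients = tibble::tibble(
        coordinate = c("L", "a", "b"),
        rss = colSums(stats::resid(fit)^2),
        n_patches = 12L
      )
    )
  }
  structure(model, class = "correction_model")
}

#' Apply a colour-correction model to a Lab raster
#'
#' Per-pixel affine maps; corrected `L*` is clipped to `[0, 100]` with the
#' clip count attached as attribute `n_clipped`. `a*` and `b*` are not
#' clipped (they have no comparable physical bound).
#'
#' @param lab a [lab_raster].
#' @param model a `correction_model` from [fit_correction()].
#' @return corrected [lab_raster] with attribute `n_clipped`.
#' @export
apply_correction <- function(lab, model) {
  stopifnot(inherits(lab, "lab_raster"), inherits(model, "correction_model"))
  arr <- unclass(lab)
  if (model$mode == "per_coordinate") {
    co <- model$coefficients
    for (k in 1:3) {
      arr[, , k] <- co$intercept[k] + co$slope[k] * arr[, , k]
    }
  } else {
    d <- dim(arr)
    m <- matrix(arr, ncol = 3L) %*% t(model$matrix)
    m <- sweep(m, 2, model$offset, "+")
    arr <- array(m, dim = d)
  }
  n_clip <- sum(arr[, , 1] < 0 | arr[, , 1] > 100)
  arr[, , 1] <- pmin(pmax(arr[, , 1], 0), 100)
  out <- lab_raster(arr)
  attr(out, "n_clipped") <- n_clip
  out
}

#' @export
print.correction_model <- function(x, ...) {
  cat("Colour-correction model (", x$mode, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a correction model
#'
#' @param x a `correction_model`.
#' @param ... unused.
#' @return tibble of per-coordinate slope, intercept and residual SS.
#' @exportS3Method generics::tidy
tidy.correction_model <- function(x, ...) x$coefficients

#' One-line summary of a correction model
#'
#' @param x a `correction_model`.
#' @param ... unused.
#' @return tibble with the mode and total residual sum of squares.
#' @exportS3Method generics::glance
glance.correction_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, total_rss = sum(x$coefficients$rss),
                 n_patches = 12L)
}
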