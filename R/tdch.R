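#' Build the two-dimensional colour-histogram grid
#'
#' The TDCH lattice over `(L*, a*)`. Each criteria value is the lower bound
#' of a half-open bin `[v, v + width)`; the defaults (`L*`: 30, 35, 40, 45,
#' width 5; `a*`: 6, 12, 18, 24, width 6) give 16 disjoint bins covering
#' `[30, 50) x [6, 30)`. Pixels outside the lattice are not counted.
#'
#' @param L_lower lower bin bounds on `L*`.
#' @param L_width bin width on `L*`.
#' @param a_lower lower bin bounds on `a*`.
#' @param a_width bin width on `a*`.
#' @return a `tdch_grid`: tibble of bins (`bin`, `L_lo`, `L_hi`, `a_lo`,
#'   `a_hi`) with the edge vectors attached as attributes.
#' @export
tdch_grid <- function(L_lower = c(30, 35, 40, 45), L_width = 5,
                      a_lower = c(6, 12, 18, 24), a_width = 6) {
  L_lower <- sort(L_lower); a_lower <- sort(a_lower)
  if (L_width <= 0 || a_width <= 0)
    stop("bin widths must be positive", call. = FALSE)
  if (any(diff(L_lower) < L_width) || any(diff(a_lower) < a_width))
    stop("bins overlap: lower bounds must be at least one width apart", call. = FALSE)
  grid <- tidyr::expand_grid(L_lo = L_lower, a_lo = a_lower) |>
    dplyr::arrange(.data$L_lo, .data$a_lo) |>
    dplyr::mutate(
      L_hi = .data$L_lo + L_width,
      a_hi = .data$a_lo + a_width,
      bin = sprintf("L%g_a%g", .data$L_lo, .data$a_lo)
    ) |>
    dplyr::select("bin", "L_lo", "L_hi", "a_lo", "a_hi")
  structure(grid, L_width = L_width, a_width = a_width,
            class = c("tdch_grid", class(grid)))
}

#' Locate the grid bin containing a point
#'
#' Half-open membership: `L_lo <= L < L_hi` and `a_lo <= a < a_hi`.
#'
#' @param grid a [tdch_grid()].
#' @param L,a coordinates (vectorised).
#' @return integer bin indices into `grid` (`NA` outside the lattice).
#' @export
tdch_bin_index <- function(grid, L, a) {
  iL <- findInterval(L, unique(grid$L_lo))
  ia <- findInterval(a, unique(grid$a_lo))
  L_lo <- unique(grid$L_lo); a_lo <- unique(grid$a_lo)
  Lw <- attr(grid, "L_width"); aw <- attr(grid, "a_width")
  okL <- iL >= 1 & L < L_lo[pmax(iL, 1)] + Lw
  oka <- ia >= 1 & a < a_lo[pmax(ia, 1)] + aw
  idx <- (iL - 1) * length(a_lo) + ia
  idx[!(okL & oka)] <- NA_integer_
  idx
}

#' Compute the two-dimensional colour histogram
#'
#' Counts valid tongue pixels per `(L*, a*)` bin and normalises by the number
#' of valid tongue pixels, so each proportion is the fraction of tongue area
#' within that colour range. Pixels outside the lattice contribute to the
#' denominator but to no bin.
#'
#' @param lab a [lab_raster].
#' @param valid a [tongue_mask] of valid pixels (post-exclusion).
#' @param grid a [tdch_grid()].
#' @return a `tdch_result`: tibble with one row per bin (`bin`, `L_lo`,
#'   `L_hi`, `a_lo`, `a_hi`, `count`, `proportion`) and the denominator as
#'   attribute `denominator`.
#' @export
compute_histogram <- function(lab, valid, grid = tdch_grid()) {
  stopifnot(inherits(lab, "lab_raster"))
  arr <- unclass(lab)
  if (!all(dim(valid) == dim(arr)[1:2]))
    stop("mask dimensions do not match the image", call. = FALSE)
  sel <- as.vector(unclass(valid))
  n <- sum(sel)
  if (n == 0) stop("empty valid mask: no tongue pixels to histogram", call. = FALSE)
  L <- as.vector(arr[, , 1])[sel]
  a <- as.vector(arr[, , 2])[sel]
  idx <- tdch_bin_index(grid, L, a)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(grid))
  out <- dplyr::mutate(tibble::as_tibble(grid),
                       count = counts, proportion = counts / n)
  structure(out, denominator = n,
            class = c("tdch_result", class(tibble::as_tibble(grid))))
}

#' Default V1-V7 bin mapping
#'
#' Assigns the seven analysis variables to grid bins. The published figure
#' fixing this assignment is not numerically specified, so this default is an
#' assumption chosen to satisfy the prose constraints (V1-V4 in the low-`a*`
#' half, V5-V7 in the high-`a*` half, V7 in the highest `L*` and `a*` ranges,
#' V1 in the lowest `L*` range, V3's `a*` range below V5's and V7's); it is
#' flagged `assumed` in output metadata and fully overridable.
#'
#' @return named character vector mapping V1..V7 to bin labels.
#' @export
default_variable_mapping <- function() {
  c(V1 = "L30_a6", V2 = "L35_a6", V3 = "L35_a12", V4 = "L40_a6",
    V5 = "L35_a18", V6 = "L40_a18", V7 = "L45_a24")
}

#' Validate a V1-V7 bin mapping
#'
#' Checks the constraint set: 7 distinct bins that exist in the grid; V1-V4
#' in the low-`a*` half and V5-V7 in the high-`a*` half; V7 with the maximal
#' `L*` and `a*` lower bounds among the seven; V1 with the minimal `L*`
#' lower bound; V3's `a*` lower bound below V5's and V7's.
#'
#' @param mapping named character vector V1..V7 -> bin label.
#' @param grid a [tdch_grid()].
#' @return `mapping`, invisibly; errors name the violated constraint.
#' @export
validate_variable_mapping <- function(mapping, grid = tdch_grid()) {
  vars <- paste0("V", 1:7)
  if (!identical(sort(names(mapping)), sort(vars)))
    stop("mapping must name exactly V1..V7", call. = FALSE)
  mapping <- mapping[vars]
  if (anyDuplicated(mapping))
    stop("mapping constraint violated: the 7 bins must be distinct", call. = FALSE)
  if (!all(mapping %in% grid$bin))
    stop("mapping refers to bins not in the grid: ",
         paste(setdiff(mapping, grid$bin), collapse = ", "), call. = FALSE)
  a_lo <- grid$a_lo[match(mapping, grid$bin)]
  L_lo <- grid$L_lo[match(mapping, grid$bin)]
  names(a_lo) <- names(L_lo) <- vars
  a_mid <- sort(unique(grid$a_lo))
  lo_half <- a_mid[ceiling(length(a_mid) / 2)]
  hi_half <- a_mid[ceiling(length(a_mid) / 2) + 1]
  if (any(a_lo[c("V1", "V2", "V3", "V4")] > lo_half))
    stop("mapping constraint violated: V1-V4 must lie in the low-a* half",
         call. = FALSE)
  if (any(a_lo[c("V5", "V6", "V7")] < hi_half))
    stop("mapping constraint violated: V5-V7 must lie in the high-a* half",
         call. = FALSE)
  if (L_lo[["V7"]] < max(L_lo) || a_lo[["V7"]] < max(a_lo))
    stop("mapping constraint violated: V7 must occupy the highest L* and a* ranges",
         call. = FALSE)
  if (L_lo[["V1"]] > min(L_lo))
    stop("mapping constraint violated: V1 must occupy the lowest L* range",
         call. = FALSE)
  if (!(a_lo[["V3"]] < a_lo[["V5"]] && a_lo[["V3"]] < a_lo[["V7"]]))
    stop("mapping constraint violated: V3's a* range must be below V5's and V7's",
         call. = FALSE)
  invisible(mapping)
}

#' Extract the V1-V7 variables from a histogram
#'
#' Copies the proportions of the mapped bins and appends the V7/V3 ratio
#' `VR` (see [v_ratio()]).
#'
#' @param result a `tdch_result` from [compute_histogram()].
#' @param mapping named character vector V1..V7 -> bin label; validated
#'   against the result's bins.
#' @return a one-row tibble with columns V1..V7 and VR (`NA` when V3 = 0),
#'   with attribute `mapping_assumed` marking the default-assignment caveat.
#' @export
extract_variables <- function(result, mapping = default_variable_mapping()) {
  grid_like <- result
  validate_variable_mapping(mapping, grid_like)
  p <- result$proportion[match(mapping[paste0("V", 1:7)], result$bin)]
  names(p) <- paste0("V", 1:7)
  vr <- v_ratio(V3 = p[["V3"]], V7 = p[["V7"]])
  out <- tibble::as_tibble(as.list(p))
  out$VR <- vr
  attr(out, "mapping_assumed") <- identical(mapping, default_variable_mapping())
  out
}

#' V7-to-V3 ratio
#'
#' `VR = V7 / V3`, an index of tongue-body red intensity (higher when the
#' bright, intensely red range dominates the pale-red range). Undefined when
#' `V3 = 0`; returned as `NA` with a warning so downstream summaries can
#' exclude it.
#'
#' @param V3,V7 bin proportions.
#' @return `V7 / V3`, or `NA` if `V3 = 0`.
#' @export
v_ratio <- function(V3, V7) {
  if (V3 == 0) {
    warning("VR undefined: V3 = 0; excluded from downstream summaries",
            call. = FALSE)
    return(NA_real_)
  }
  V7 / V3
}

#' @export
print.tdch_result <- function(x, ...) {
  cat(sprintf("TDCH over %d bins, denominator = %d valid pixels\n",
              nrow(x), attr(x, "denominator")))
  NextMethod()
}

#' Plot a TDCH result as a (L*, a*) tile map
#'
#' @param object a `tdch_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tdch_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$L_lo + .data$L_hi) / 2,
    y = (.data$a_lo + .data$a_hi) / 2,
    fill = .data$proportion
  )) +
    ggplot2::geom_tile(ggplot2::aes(
      width = .data$L_hi - .data$L_lo,
      height = .data$a_hi - .data$a_lo
    ), colour = "grey30") +
    ggplot2::scale_fill_viridis_c(name = "proportion") +
    ggplot2::labs(x = "L* (lightness)", y = "a* (red-green)",
                  title = "Two-dimensional colour histogram") +
    ggplot2::theme_minimal()
}
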