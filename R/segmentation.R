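#' Polar edge map
#'
#' Radial edge strength of the `L*` channel about a centre point: the
#' magnitude of the directional derivative of `L*` along the outward radial
#' direction. Radially oriented lightness transitions (such as the tongue
#' boundary seen from inside the tongue) give strong responses; tangential
#' texture gives weak ones. Invariant to adding a constant to `L*`.
#'
#' @param lab a [lab_raster].
#' @param center numeric `(row, col)` centre, 1-based, inside the image.
#' @return a non-negative edge-strength matrix of image dimensions.
#' @export
polar_edge_map <- function(lab, center) {
  stopifnot(inherits(lab, "lab_raster"))
  L <- unclass(lab)[, , 1]
  h <- nrow(L); w <- ncol(L)
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w)
    stop("center must lie inside the image", call. = FALSE)
  g <- gradient2d(L)
  dr <- outer(seq_len(h) - center[1], rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - center[2])
  rad <- sqrt(dr^2 + dc^2)
  rad[rad == 0] <- 1
  abs(g$gy * dr / rad + g$gx * dc / rad)
}

# central-difference gradient; gy along rows (y), gx along columns (x)
gradient2d <- function(M) {
  h <- nrow(M); w <- ncol(M)
  gy <- M; gx <- M
  if (h >= 3) gy[2:(h - 1), ] <- (M[3:h, ] - M[1:(h - 2), ]) / 2
  gy[1, ] <- M[min(2, h), ] - M[1, ]
  gy[h, ] <- M[h, ] - M[max(h - 1, 1), ]
  if (w >= 3) gx[, 2:(w - 1)] <- (M[, 3:w] - M[, 1:(w - 2)]) / 2
  gx[, 1] <- M[, min(2, w)] - M[, 1]
  gx[, w] <- M[, w] - M[, max(w - 1, 1)]
  list(gy = gy, gx = gx)
}

laplacian2d <- function(M) {
  h <- nrow(M); w <- ncol(M)
  up <- M[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- M[c(seq(2, h), h), , drop = FALSE]
  lf <- M[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- M[, c(seq(2, w), w), drop = FALSE]
  up + dn + lf + rt - 4 * M
}

#' Gradient vector flow field
#'
#' Diffuses the gradient of an edge map into homogeneous regions by iterating
#' the standard GVF update
#' `u <- u + mu * laplacian(u) - (fx^2 + fy^2) * (u - fx)` (and likewise for
#' `v`), extending the capture range of the snake far beyond the edges.
#'
#' @param edges non-negative edge-strength matrix.
#' @param mu regularisation weight (`> 0`; explicit iteration is stable for
#'   `mu <= 0.25` on the unit grid).
#' @param n_iter number of diffusion iterations (`>= 1`).
#' @return a list with matrices `u` (column/x component) and `v` (row/y
#'   component), class `gvf_field`.
#' @export
gvf <- function(edges, mu = 0.2, n_iter = 80) {
  if (!is.matrix(edges)) stop("edges must be a matrix", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  f <- edges
  rng <- max(f) - min(f)
  if (rng > 0) f <- (f - min(f)) / rng
  g <- gradient2d(f)
  fx <- g$gx; fy <- g$gy
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  for (i in seq_len(n_iter)) {
    u <- u + mu * laplacian2d(u) - b * (u - fx)
    v <- v + mu * laplacian2d(v) - b * (v - fy)
  }
  structure(list(u = u, v = v), class = "gvf_field")
}

#' Evolve an active contour (snake) in an external force field
#'
#' Semi-implicit snake evolution: internal tension/rigidity handled by a
#' cyclic pentadiagonal system solved once, external force interpolated
#' bilinearly at vertex positions. Vertices are clamped to the image bounds
#' and resampled to uniform arc length every few iterations.
#'
#' @param init closed contour: numeric matrix with columns `row`, `col`
#'   (at least 8 vertices).
#' @param field a `gvf_field` (list with `u`, `v` matrices).
#' @param alpha tension (first-derivative) weight.
#' @param beta rigidity (second-derivative) weight.
#' @param step time step.
#' @param n_iter maximum iterations.
#' @param tol convergence threshold on the maximum vertex displacement
#'   (pixels) between resampling-free iterations.
#' @param kappa scaling of the external force.
#' @return converged contour matrix (columns `row`, `col`), attribute
#'   `converged` logical and `iterations` used.
#' @export
evolve_snake <- function(init, field, alpha = 0.1, beta = 0.05, step = 1,
                         n_iter = 300, tol = 0.1, kappa = 2) {
  if (!is.matrix(init) || ncol(init) != 2L || nrow(init) < 8L)
    stop("init must be a closed contour with >= 8 (row, col) vertices", call. = FALSE)
  h <- nrow(field$u); w <- ncol(field$u)
  n <- nrow(init)
  A <- snake_matrix(n, alpha, beta)
  Inv <- solve(diag(n) + step * A)
  y <- init[, 1]; x <- init[, 2]
  converged <- FALSE; it <- 0
  for (it in seq_len(n_iter)) {
    fu <- bilinear(field$u, y, x)
    fv <- bilinear(field$v, y, x)
    y_new <- as.vector(Inv %*% (y + step * kappa * fv))
    x_new <- as.vector(Inv %*% (x + step * kappa * fu))
    y_new <- pmin(pmax(y_new, 1), h)
    x_new <- pmin(pmax(x_new, 1), w)
    disp <- max(abs(y_new - y), abs(x_new - x))
    y <- y_new; x <- x_new
    if (it %% 10 == 0) {
      rs <- resample_contour(cbind(y, x), n)
      y <- rs[, 1]; x <- rs[, 2]
    } else if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  out <- cbind(row = y, col = x)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

# bright-object mask: threshold at the midpoint between the low and high
# ends of the L* distribution (robust to objects smaller than a quartile)
bright_region <- function(L) {
  thr <- mean(stats::quantile(L, c(0.05, 0.995)))
  b <- L >= thr
  if (!any(b)) b <- L >= stats::quantile(L, 0.75)
  b
}

# cyclic internal-energy matrix: alpha * D2 + beta * D4 (penta-diagonal)
snake_matrix <- function(n, alpha, beta) {
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  A <- matrix(0, n, n)
  a <- 2 * alpha + 6 * beta
  b <- -alpha - 4 * beta
  c <- beta
  for (k in seq_len(n)) {
    A[k, k] <- a
    A[k, idx(1)[k]] <- b
    A[k, idx(-1)[k]] <- b
    A[k, idx(2)[k]] <- c
    A[k, idx(-2)[k]] <- c
  }
  A
}

bilinear <- function(M, y, x) {
  h <- nrow(M); w <- ncol(M)
  y <- pmin(pmax(y, 1), h); x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  if (h == 1) y0 <- rep(1, length(y))
  if (w == 1) x0 <- rep(1, length(x))
  dy <- y - y0; dx <- x - x0
  i00 <- cbind(y0, x0); i10 <- cbind(pmin(y0 + 1, h), x0)
  i01 <- cbind(y0, pmin(x0 + 1, w)); i11 <- cbind(pmin(y0 + 1, h), pmin(x0 + 1, w))
  M[i00] * (1 - dy) * (1 - dx) + M[i10] * dy * (1 - dx) +
    M[i01] * (1 - dy) * dx + M[i11] * dy * dx
}

# resample closed contour to n vertices uniformly spaced in arc length
resample_contour <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts)
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  y <- stats::approx(s, closed[, 1], xout = target, rule = 2)$y
  x <- stats::approx(s, closed[, 2], xout = target, rule = 2)$y
  cbind(y, x)
}

#' Fill the interior of a closed contour (even-odd rule)
#'
#' Scanline polygon fill: a pixel belongs to the mask if its (integer) centre
#' is inside the polygon by the even-odd crossing rule.
#'
#' @param contour matrix with columns `row`, `col`.
#' @param dims `c(height, width)` of the target mask.
#' @return logical matrix.
#' @export
contour_to_mask <- function(contour, dims) {
  h <- dims[1]; w <- dims[2]
  y <- contour[, 1]; x <- contour[, 2]
  n <- length(y)
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  mask <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    crosses <- ((y <= r) & (y2 > r)) | ((y2 <= r) & (y > r))
    if (!any(crosses)) next
    t <- (r - y[crosses]) / (y2[crosses] - y[crosses])
    xs <- sort(x[crosses] + t * (x2[crosses] - x[crosses]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (hi >= lo) mask[r, max(lo, 1):min(hi, w)] <- TRUE
    }
  }
  mask
}

#' Segment the tongue region
#'
#' Automatic delineation: a polar edge map of `L*` about a centre (supplied
#' or auto-estimated as the centroid of the brightest `L*` quartile), gradient
#' vector flow of that edge map, then a snake initialised as a circle around
#' the bright region and evolved to the tongue boundary. The returned mask is
#' the even-odd interior of the converged contour.
#'
#' @param lab a [lab_raster].
#' @param center optional `(row, col)` centre; auto-estimated when `NULL`.
#' @param params list of snake/GVF parameters; see [segmentation_params()].
#' @return a [tongue_mask] (provenance `"auto"`) with the converged contour
#'   attached as attribute `contour`.
#' @export
segment_tongue <- function(lab, center = NULL, params = segmentation_params()) {
  stopifnot(inherits(lab, "lab_raster"))
  L <- unclass(lab)[, , 1]
  h <- nrow(L); w <- ncol(L)
  if (max(L) - min(L) < 1e-9)
    stop("segmentation failed: image is constant, no tongue-like region", call. = FALSE)
  bright <- bright_region(L)
  if (is.null(center)) {
    idx <- which(bright, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  edges <- polar_edge_map(lab, center)
  field <- gvf(edges, mu = params$mu, n_iter = params$gvf_iter)
  # elliptical initialisation from the bright region's second moments
  # (for a uniform ellipse the semi-axis is twice the SD along that axis)
  idx <- which(bright, arr.ind = TRUE)
  S <- stats::cov(cbind(idx[, 1], idx[, 2]))
  eig <- eigen(S, symmetric = TRUE)
  ax <- params$init_radius_factor * 2 * sqrt(pmax(eig$values, 1))
  theta <- seq(0, 2 * pi, length.out = params$n_vertices + 1)[-(params$n_vertices + 1)]
  pts <- eig$vectors %*% rbind(ax[1] * cos(theta), ax[2] * sin(theta))
  init <- cbind(pmin(pmax(center[1] + pts[1, ], 1), h),
                pmin(pmax(center[2] + pts[2, ], 1), w))
  contour <- evolve_snake(init, field,
                          alpha = params$alpha, beta = params$beta,
                          step = params$step, n_iter = params$snake_iter,
                          tol = params$tol, kappa = params$kappa)
  mask <- contour_to_mask(contour, c(h, w))
  if (!any(mask))
    stop("segmentation failed: contour collapsed to an empty interior; ",
         "supply a manual mask", call. = FALSE)
  out <- tongue_mask(mask, provenance = "auto")
  attr(out, "contour") <- contour
  out
}

#' Default segmentation parameters
#'
#' Common GVF-snake settings: `alpha` tension 0.1, `beta` rigidity 0.05,
#' GVF `mu` 0.2 with 400 diffusion iterations (the diffusion length, about
#' `sqrt(4 * mu * n_iter)` pixels, sets the snake's capture range; 400
#' iterations give roughly 18 px), 300 snake iterations, 0.1 px convergence
#' tolerance. `init_radius_factor` scales the initial ellipse relative to
#' the second moments of the bright region.
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
segmentation_params <- function(...) {
  p <- list(alpha = 0.1, beta = 0.05, mu = 0.2, gvf_iter = 400,
            snake_iter = 300, tol = 0.1, step = 1, kappa = 2,
            n_vertices = 120, init_radius_factor = 1.15)
  override <- list(...)
  p[names(override)] <- override
  p
}

#' Merge automatic and manual masks
#'
#' `(auto ∪ add) \ remove`, the manual-refinement step applied after
#' automatic segmentation.
#'
#' @param auto automatic [tongue_mask].
#' @param manual_add logical matrix of pixels to add (or `NULL`).
#' @param manual_remove logical matrix of pixels to remove (or `NULL`).
#' @return a [tongue_mask] with provenance `"merged"`; warns if empty.
#' @export
merge_manual <- function(auto, manual_add = NULL, manual_remove = NULL) {
  m <- unclass(auto)
  if (!is.null(manual_add)) {
    if (!all(dim(manual_add) == dim(m)))
      stop("manual_add dimensions do not match the automatic mask", call. = FALSE)
    m <- m | manual_add
  }
  if (!is.null(manual_remove)) {
    if (!all(dim(manual_remove) == dim(m)))
      stop("manual_remove dimensions do not match the automatic mask", call. = FALSE)
    m <- m & !manual_remove
  }
  if (!any(m)) warning("merged mask is empty", call. = FALSE)
  tongue_mask(m, provenance = "merged")
}
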