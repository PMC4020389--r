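#' Tongue phantom specification
#'
#' Describes a synthetic tongue photograph with exact ground truth: an
#' elliptical tongue body whose pixel colours are drawn from a mixture over
#' TDCH bins, an optional coating patch of distinct colour, specular
#' highlight spots (`L* > 85`), a dark root band (`L* < 30`), an optional
#' embedded 12-patch colour checker, and an optional per-coordinate affine
#' colour distortion emulating device error (which the checker-based
#' correction must undo). Colours are specified in Lab and rendered through
#' [lab_to_srgb()] so that pipeline recovery is a true round trip.
#'
#' Jittered body colours are clamped to stay `bin_margin` inside their
#' assigned bin so the assignment map remains exact ground truth through the
#' 8-bit render/recover round trip.
#'
#' @param width,height image size in pixels.
#' @param center ellipse centre `(row, col)`.
#' @param axes ellipse semi-axes `(rows, cols)`.
#' @param rotation ellipse rotation, degrees.
#' @param body_bins named numeric vector: target mixture proportions over
#'   TDCH bin labels (must sum to 1).
#' @param body_b fixed `b*` value of body colours.
#' @param jitter_sd Lab-space Gaussian jitter SD.
#' @param bin_margin clamp margin inside each bin (Lab units).
#' @param coating logical: add a coating patch.
#' @param coating_bin TDCH bin of the coating colour.
#' @param specular_frac approximate fraction of tongue pixels turned into
#'   specular spots (`L* = 92`).
#' @param root_frac approximate fraction of tongue pixels in the dark root
#'   band (`L* = 15`).
#' @param checker logical: embed the colour checker.
#' @param distortion `NULL` for none, else list with `slope` and `offset`
#'   length-3 numeric vectors (L, a, b): rendered = slope * true + offset.
#' @param seed RNG seed; the generator is seed-deterministic.
#' @return a `tongue_phantom_spec` list.
#' @export
tongue_phantom_spec <- function(width = 180, height = 180,
                                center = c(100, 100), axes = c(55, 45),
                                rotation = 0,
                                body_bins = c(L40_a18 = 0.5, L35_a12 = 0.3,
                                              L45_a24 = 0.2),
                                body_b = 12, jitter_sd = 0.8, bin_margin = 0.7,
                                coating = FALSE, coating_bin = "L40_a6",
                                specular_frac = 0, root_frac = 0,
                                checker = FALSE, distortion = NULL,
                                seed = 1) {
  if (abs(sum(body_bins) - 1) > 1e-9)
    stop("body_bins proportions must sum to 1", call. = FALSE)
  grid <- tdch_grid()
  bad <- setdiff(c(names(body_bins), if (coating) coating_bin), grid$bin)
  if (length(bad))
    stop("unknown TDCH bin(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (center[1] - axes[1] < 1 || center[1] + axes[1] > height ||
      center[2] - axes[2] < 1 || center[2] + axes[2] > width)
    stop("ellipse must lie inside the image", call. = FALSE)
  structure(as.list(environment()), class = "tongue_phantom_spec")
}

#' Generate a synthetic tongue image with ground truth
#'
#' Renders the phantom described by a [tongue_phantom_spec()] and returns
#' the image together with exact ground-truth masks and bin proportions.
#'
#' @param spec a [tongue_phantom_spec()].
#' @return a list: `image` ([rgb_raster]), `tongue` (ground-truth
#'   [tongue_mask]), `excluded` (ground-truth mask of specular + root
#'   pixels), `proportions` (named 16-vector of true bin proportions over
#'   valid pixels), `checker_regions` (patch rectangles or `NULL`),
#'   `center`, `lab_true` (undistorted [lab_raster]), `spec`.
#' @export
generate_tongue_image <- function(spec) {
  stopifnot(inherits(spec, "tongue_phantom_spec"))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  grid <- tdch_grid()

  rr <- outer(seq_len(h), rep(1, w)) - spec$center[1]
  cc <- outer(rep(1, h), seq_len(w)) - spec$center[2]
  th <- spec$rotation * pi / 180
  u <- cos(th) * rr + sin(th) * cc
  v <- -sin(th) * rr + cos(th) * cc
  tongue <- (u / spec$axes[1])^2 + (v / spec$axes[2])^2 <= 1
  n_tongue <- sum(tongue)

  # per-pixel Lab, background first
  L <- matrix(18, h, w); A <- matrix(2, h, w); B <- matrix(2, h, w)

  # body mixture assignment: contiguous angular sectors with areas matching
  # the target proportions (a spatially coherent colour field, as on a real
  # tongue; iid per-pixel assignment would create salt-and-pepper edges)
  bins <- names(spec$body_bins)
  assign_bin <- matrix(NA_character_, h, w)
  # angle in the axis-normalised frame, where sector angle is exactly
  # proportional to sector area
  ang <- atan2(v / spec$axes[2], u / spec$axes[1])
  ang0 <- stats::runif(1, -pi, pi)
  frac <- ((ang - ang0) / (2 * pi)) %% 1
  breaks <- cumsum(spec$body_bins) / sum(spec$body_bins)
  sector <- findInterval(frac, c(0, breaks), rightmost.closed = TRUE)
  sector <- pmin(sector, length(bins))
  assign_bin[tongue] <- bins[sector[tongue]]

  # coating patch: upper-central blob overriding the body assignment
  if (spec$coating) {
    blob <- tongue & ((u + 0.45 * spec$axes[1]) / (0.45 * spec$axes[1]))^2 +
      (v / (0.55 * spec$axes[2]))^2 <= 1
    assign_bin[blob] <- spec$coating_bin
  }

  # jittered colours clamped inside the assigned bin
  idx <- which(tongue)
  bin_rows <- match(assign_bin[idx], grid$bin)
  Lc <- (grid$L_lo[bin_rows] + grid$L_hi[bin_rows]) / 2
  Ac <- (grid$a_lo[bin_rows] + grid$a_hi[bin_rows]) / 2
  m <- spec$bin_margin
  L[idx] <- pmin(pmax(Lc + stats::rnorm(length(idx), 0, spec$jitter_sd),
                      grid$L_lo[bin_rows] + m), grid$L_hi[bin_rows] - m)
  A[idx] <- pmin(pmax(Ac + stats::rnorm(length(idx), 0, spec$jitter_sd),
                      grid$a_lo[bin_rows] + m), grid$a_hi[bin_rows] - m)
  B[idx] <- pmin(pmax(spec$body_b + stats::rnorm(length(idx), 0, spec$jitter_sd),
                      0), 35)

  # dark root band: top slice of the ellipse (in the ellipse frame)
  excluded <- matrix(FALSE, h, w)
  if (spec$root_frac > 0) {
    qs <- stats::quantile(u[tongue], spec$root_frac)
    root <- tongue & (u <= qs)
    L[root] <- 15; A[root] <- 4; B[root] <- 4
    excluded <- excluded | root
  }

  # specular spots: seeded disks inside the ellipse until the target count
  if (spec$specular_frac > 0) {
    target <- round(spec$specular_frac * n_tongue)
    spot <- matrix(FALSE, h, w)
    cand <- which(tongue & !excluded)
    while (sum(spot) < target && length(cand) > 0) {
      ctr <- arrayInd(cand[sample.int(length(cand), 1)], c(h, w))
      rad <- 3
      d2 <- (outer(seq_len(h), rep(1, w)) - ctr[1])^2 +
        (outer(rep(1, h), seq_len(w)) - ctr[2])^2
      disk <- d2 <= rad^2 & tongue & !excluded
      spot <- spot | disk
    }
    if (sum(spot) > target) {
      on_idx <- which(spot)
      spot[on_idx[seq(target + 1, length(on_idx))]] <- FALSE
    }
    L[spot] <- 92; A[spot] <- 2; B[spot] <- 2
    excluded <- excluded | spot
  }

  # checker strip: 6 rows x 2 columns of patches at the top-left
  checker_regions <- NULL
  if (spec$checker) {
    ref <- checker_reference()
    ps <- 12; gap <- 3
    checker_regions <- purrr::map_dfr(seq_len(12), function(i) {
      rrow <- (i - 1) %% 6; rcol <- (i - 1) %/% 6
      tibble::tibble(patch_id = ref$patch_id[i],
                     row0 = 4 + rrow * (ps + gap),
                     row1 = 3 + rrow * (ps + gap) + ps,
                     col0 = 4 + rcol * (ps + gap),
                     col1 = 3 + rcol * (ps + gap) + ps)
    })
    for (i in seq_len(12)) {
      r <- checker_regions[i, ]
      L[r$row0:r$row1, r$col0:r$col1] <- ref$L_ref[i]
      A[r$row0:r$row1, r$col0:r$col1] <- ref$a_ref[i]
      B[r$row0:r$row1, r$col0:r$col1] <- ref$b_ref[i]
    }
  }

  lab_true <- lab_raster(array(c(L, A, B), dim = c(h, w, 3)))

  # device distortion, then render to 8-bit sRGB
  lab_out <- lab_true
  if (!is.null(spec$distortion)) {
    arr <- unclass(lab_true)
    for (k in 1:3)
      arr[, , k] <- spec$distortion$slope[k] * arr[, , k] +
        spec$distortion$offset[k]
    arr[, , 1] <- pmin(pmax(arr[, , 1], 0), 100)
    lab_out <- lab_raster(arr)
  }
  image <- lab_to_srgb(lab_out)

  valid <- tongue & !excluded
  counts <- table(factor(assign_bin[valid], levels = grid$bin))
  proportions <- as.numeric(counts) / sum(valid)
  names(proportions) <- grid$bin

  list(image = image, tongue = tongue_mask(tongue, "manual"),
       excluded = excluded, proportions = proportions,
       checker_regions = checker_regions, center = spec$center,
       lab_true = lab_true, spec = spec)
}

#' Build the 20-ellipse phantom suite used to benchmark segmentation
#'
#' Twenty ellipse variants spanning axis ratios 1.2-2.0 and rotations
#' 0-30 degrees, rendered without checker, coating or artefacts.
#'
#' @param seed base seed; phantom `i` uses `seed + i`.
#' @param noise_sd optional Gaussian pixel noise (8-bit units) added to the
#'   rendered image.
#' @return list of 20 phantom results as from [generate_tongue_image()].
#' @export
phantom_suite <- function(seed = 100, noise_sd = 0) {
  ratios <- seq(1.2, 2.0, length.out = 5)
  rots <- seq(0, 30, length.out = 4)
  cases <- tidyr::expand_grid(ratio = ratios, rot = rots)
  cases$i <- seq_len(nrow(cases))
  purrr::pmap(cases, function(ratio, rot, i) {
    b <- 38
    sp <- tongue_phantom_spec(axes = c(round(ratio * b), b), rotation = rot,
                              seed = seed + i)
    ph <- generate_tongue_image(sp)
    if (noise_sd > 0) {
      old <- .Random.seed_exists(); on.exit(restore_seed(old), add = TRUE)
      set.seed(seed + 1000 + i)
      arr <- unclass(ph$image)
      arr <- pmin(pmax(arr + stats::rnorm(length(arr), 0, noise_sd), 0), 255)
      ph$image <- rgb_raster(arr)
    }
    ph
  })
}
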