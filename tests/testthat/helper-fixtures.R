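# Shared fixtures, all built in code.

# bright disk (L = L_in) on dark ground (L = L_out), neutral chroma
disk_lab <- function(size = 101, radius = 30, L_in = 60, L_out = 20,
                     center = NULL) {
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  d2 <- outer((seq_len(size) - center[1])^2, (seq_len(size) - center[2])^2, "+")
  L <- ifelse(d2 <= radius^2, L_in, L_out)
  lab_raster(array(c(L, L * 0, L * 0), dim = c(size, size, 3)))
}

# random Lab raster spanning (and overflowing) the default TDCH lattice
random_lab <- function(h, w, seed) {
  set.seed(seed)
  L <- matrix(runif(h * w, 25, 55), h, w)
  a <- matrix(runif(h * w, 0, 35), h, w)
  b <- matrix(runif(h * w, -10, 30), h, w)
  lab_raster(array(c(L, a, b), dim = c(h, w, 3)))
}

full_mask <- function(h, w) tongue_mask(matrix(TRUE, h, w), "manual")

# independent brute-force TDCH oracle: naive per-pixel double loop
brute_force_tdch <- function(lab, valid, grid) {
  arr <- unclass(lab)
  counts <- numeric(nrow(grid))
  denom <- 0
  for (r in seq_len(nrow(arr))) {
    for (c in seq_len(ncol(arr))) {
      if (!valid[r, c]) next
      denom <- denom + 1
      L <- arr[r, c, 1]; a <- arr[r, c, 2]
      for (k in seq_len(nrow(grid))) {
        if (L >= grid$L_lo[k] && L < grid$L_hi[k] &&
            a >= grid$a_lo[k] && a < grid$a_hi[k]) {
          counts[k] <- counts[k] + 1
          break
        }
      }
    }
  }
  list(counts = counts, proportions = counts / denom, denominator = denom)
}

# explicit normal-equations solver for y ~ 1 + x (independent of lm)
normal_eq_fit <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y) # (intercept, slope)
}

# independent bilinear sampler used to probe fields along rays
bilinear_probe <- function(M, y, x) {
  h <- nrow(M); w <- ncol(M)
  y <- pmin(pmax(y, 1), h); x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  dy <- y - y0; dx <- x - x0
  M[cbind(y0, x0)] * (1 - dy) * (1 - dx) +
    M[cbind(y0 + 1, x0)] * dy * (1 - dx) +
    M[cbind(y0, x0 + 1)] * (1 - dy) * dx +
    M[cbind(y0 + 1, x0 + 1)] * dy * dx
}
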