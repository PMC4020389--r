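test_that("polar edge map is zero on constant images and peaks on a disk boundary", {
  flat <- lab_raster(array(c(rep(40, 25), rep(0, 50)), dim = c(5, 5, 3)))
  expect_true(all(polar_edge_map(flat, c(3, 3)) == 0))

  lab <- disk_lab(size = 101, radius = 30)
  e <- polar_edge_map(lab, c(51, 51))
  expect_true(all(e >= 0))
  # argmax radius within 1 px of the true boundary along several rays
  for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
    r <- 1:48
    prof <- bilinear_probe(e, 51 + r * sin(ang), 51 + r * cos(ang))
    expect_lt(abs(r[which.max(prof)] - 30), 1.5)
  }
})

test_that("polar edge map is equivariant under translation and invariant to L* offsets", {
  a <- disk_lab(size = 81, radius = 20, center = c(41, 41))
  b <- disk_lab(size = 81, radius = 20, center = c(46, 38))
  ea <- polar_edge_map(a, c(41, 41))
  eb <- polar_edge_map(b, c(46, 38))
  # compare away from the image border
  expect_equal(ea[16:60, 16:60], eb[(16 + 5):(60 + 5), (16 - 3):(60 - 3)],
               tolerance = 1e-12)

  shifted <- unclass(a)
  shifted[, , 1] <- shifted[, , 1] + 25
  expect_equal(polar_edge_map(lab_raster(shifted), c(41, 41)), ea,
               tolerance = 1e-12)
})

test_that("polar edge map rejects an outside center", {
  expect_error(polar_edge_map(disk_lab(41, 10), c(0, 5)), "inside")
})

test_that("gvf validates inputs and vanishes on a zero edge map", {
  z <- matrix(0, 20, 20)
  f <- gvf(z, mu = 0.2, n_iter = 5)
  expect_true(all(f$u == 0) && all(f$v == 0))
  expect_error(gvf(z, mu = 0), "positive")
  expect_error(gvf(z, n_iter = 0), "n_iter")
})

test_that("one gvf step with tiny mu reproduces the edge-map gradient at edges", {
  e <- polar_edge_map(disk_lab(61, 15), c(31, 31))
  f <- gvf(e, mu = 1e-6, n_iter = 1)
  en <- (e - min(e)) / (max(e) - min(e))
  gx <- (cbind(en[, -1], en[, ncol(en)]) - cbind(en[, 1], en[, -ncol(en)])) / 2
  strong <- en > 0.5
  expect_lt(max(abs(f$u[strong] - gx[strong])), 1e-3)
})

test_that("gvf magnitude decays with distance from an isolated edge ring", {
  e <- polar_edge_map(disk_lab(101, 30), c(51, 51))
  f <- gvf(e, n_iter = 200)
  mag <- sqrt(f$u^2 + f$v^2)
  r <- 1:18
  prof <- bilinear_probe(mag, 51 + 30 + r, rep(51, 18))
  # smoothed monotone decay outward from the ring
  expect_true(all(diff(stats::filter(prof, rep(1 / 3, 3))[2:16]) < 0))
})

test_that("snake is a fixed point under zero field and zero internal energy", {
  field <- list(u = matrix(0, 50, 50), v = matrix(0, 50, 50))
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  init <- cbind(25 + 8 * sin(th), 25 + 8 * cos(th))
  out <- evolve_snake(init, field, alpha = 0, beta = 0, n_iter = 9, tol = 1e-8)
  expect_equal(unclass(out)[, 1], init[, 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(evolve_snake(init[1:5, ], field), "8")
})

test_that("snake converges onto a disk boundary from either side", {
  lab <- disk_lab(101, 30)
  f <- gvf(polar_edge_map(lab, c(51, 51)), n_iter = 400)
  th <- seq(0, 2 * pi, length.out = 81)[-81]
  radius_of <- function(r0) {
    init <- cbind(51 + r0 * sin(th), 51 + r0 * cos(th))
    s <- evolve_snake(init, f)
    sqrt((s[, 1] - 51)^2 + (s[, 2] - 51)^2)
  }
  r_out <- radius_of(40)
  expect_lt(mean(abs(r_out - 30)), 1)
  r_in <- radius_of(22)
  expect_lt(mean(abs(r_in - r_out)), 1)
})

test_that("internal energy contracts monotonically under zero field", {
  field <- list(u = matrix(0, 60, 60), v = matrix(0, 60, 60))
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  pts <- cbind(30 + 12 * sin(th) + rnorm(24, 0, 0.5),
               30 + 12 * cos(th) + rnorm(24, 0, 0.5))
  internal_energy <- function(p) {
    d1 <- rbind(diff(p), p[1, ] - p[nrow(p), ])
    d2 <- rbind(diff(d1), d1[1, ] - d1[nrow(d1), ])
    0.1 * sum(d1^2) + 0.05 * sum(d2^2)
  }
  energies <- numeric(8)
  for (i in seq_len(8)) {
    pts <- unclass(evolve_snake(pts, field, n_iter = 1, tol = 0))[, 1:2]
    energies[i] <- internal_energy(pts)
  }
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("automatic segmentation recovers phantom tongues with high Dice", {
  ph <- generate_tongue_image(tongue_phantom_spec(seed = 3))
  m <- segment_tongue(srgb_to_lab(ph$image))
  expect_s3_class(m, "tongue_mask")
  expect_identical(attr(m, "provenance"), "auto")
  expect_gte(dice_coefficient(m, ph$tongue), 0.95)

  # noisy variant
  set.seed(12)
  arr <- pmin(pmax(unclass(ph$image) + rnorm(length(ph$image), 0, 5), 0), 255)
  m_noisy <- segment_tongue(srgb_to_lab(rgb_raster(arr)))
  expect_gte(dice_coefficient(m_noisy, ph$tongue), 0.90)

  expect_error(segment_tongue(lab_raster(array(0, c(40, 40, 3)))), "constant")
})

test_that("manual merge is exact set arithmetic with provenance tracking", {
  set.seed(4)
  auto <- tongue_mask(matrix(runif(400) > 0.5, 20, 20), "auto")
  add <- matrix(runif(400) > 0.8, 20, 20)
  rem <- matrix(runif(400) > 0.8, 20, 20)
  merged <- merge_manual(auto, add, rem)
  # brute-force per-pixel oracle
  expected <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20)
    expected[r, c] <- (auto[r, c] || add[r, c]) && !rem[r, c]
  expect_equal(unclass(merged)[, ], expected, ignore_attr = TRUE)
  expect_identical(attr(merged, "provenance"), "merged")

  expect_equal(sum(merge_manual(auto)), sum(auto))
  expect_warning(merge_manual(auto, manual_remove = unclass(auto)[, ] | TRUE),
                 "empty")
  expect_error(merge_manual(auto, matrix(TRUE, 5, 5)), "dimensions")
})
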