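test_that("checker sampling returns exact means over patch regions", {
  arr <- array(0, c(20, 20, 3))
  arr[, , 1] <- 50; arr[, , 2] <- 5; arr[, , 3] <- -3
  arr[1:4, 1:4, 1] <- 72.5 # half 72.5 / half 50 region below
  lab <- lab_raster(array(pmax(arr, 0), c(20, 20, 3)))

  ref <- checker_reference()
  regions <- tibble::tibble(
    patch_id = ref$patch_id,
    row0 = rep(c(6, 11), 6)[1:12], row1 = rep(c(9, 14), 6)[1:12],
    col0 = rep(1:6 * 3 - 2, each = 2), col1 = rep(1:6 * 3, each = 2)
  )
  cs <- sample_checker(lab, regions)
  expect_s3_class(cs, "checker_set")
  expect_true(all(cs$L_meas == 50))
  expect_true(all(cs$a_meas == 5))

  # half/half region -> midpoint
  r2 <- regions; r2$row0[1] <- 1; r2$row1[1] <- 8; r2$col0[1] <- 1; r2$col1[1] <- 4
  cs2 <- sample_checker(lab, r2)
  expect_equal(cs2$L_meas[cs2$patch_id == ref$patch_id[1]], (72.5 + 50) / 2)

  bad <- regions; bad$row1[3] <- 40
  expect_error(sample_checker(lab, bad), "outside")
  small <- regions; small$row1[2] <- small$row0[2]; small$col1[2] <- small$col0[2]
  expect_error(sample_checker(lab, small), "4 px")
})

test_that("noisy patch means concentrate at the truth", {
  set.seed(9)
  arr <- array(0, c(20, 20, 3))
  arr[, , 1] <- 60 + rnorm(400, 0, 1)
  lab <- lab_raster(array(pmax(pmin(arr, 100), 0), c(20, 20, 3)))
  m <- mean(unclass(lab)[, , 1])
  expect_lt(abs(m - 60), 3 * 1 / sqrt(400))
})

test_that("identity measurements give an identity fit with zero residual", {
  ref <- checker_reference()
  cs <- checker_set(tibble::tibble(L_meas = ref$L_ref, a_meas = ref$a_ref,
                                   b_meas = ref$b_ref))
  m <- fit_correction(cs)
  expect_equal(m$coefficients$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(m$coefficients$intercept, rep(0, 3), tolerance = 1e-10)
  expect_equal(m$coefficients$rss, rep(0, 3), tolerance = 1e-18)
})

test_that("a known affine distortion is recovered exactly", {
  ref <- checker_reference()
  cs <- checker_set(tibble::tibble(
    L_meas = (ref$L_ref - 3) / 0.9,
    a_meas = (ref$a_ref + 2) / 1.1,
    b_meas = (ref$b_ref - 1) / 0.8
  ))
  m <- fit_correction(cs)
  co <- m$coefficients
  expect_equal(co$slope, c(0.9, 1.1, 0.8), tolerance = 1e-9)
  expect_equal(co$intercept, c(3, -2, 1), tolerance = 1e-9)
})

test_that("fit equals the explicit normal-equations solution on random data", {
  set.seed(14)
  for (i in 1:5) {
    ref <- checker_reference()
    meas <- tibble::tibble(
      L_meas = ref$L_ref + rnorm(12, 0, 2),
      a_meas = ref$a_ref + rnorm(12, 0, 2),
      b_meas = ref$b_ref + rnorm(12, 0, 2)
    )
    m <- fit_correction(checker_set(meas))
    achro <- 1:6; chrom <- 7:12
    oL <- normal_eq_fit(meas$L_meas[achro], ref$L_ref[achro])
    oa <- normal_eq_fit(meas$a_meas[chrom], ref$a_ref[chrom])
    ob <- normal_eq_fit(meas$b_meas[chrom], ref$b_ref[chrom])
    expect_equal(m$coefficients$intercept, c(oL[1], oa[1], ob[1]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(m$coefficients$slope, c(oL[2], oa[2], ob[2]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("least-squares optimality: perturbing coefficients never lowers the RSS", {
  set.seed(15)
  ref <- checker_reference()
  meas <- tibble::tibble(L_meas = ref$L_ref + rnorm(12, 0, 1.5),
                         a_meas = ref$a_ref + rnorm(12, 0, 1.5),
                         b_meas = ref$b_ref + rnorm(12, 0, 1.5))
  m <- fit_correction(checker_set(meas))
  co <- m$coefficients
  rss_of <- function(slope, icpt, x, y) sum((y - icpt - slope * x)^2)
  sets <- list(list(x = meas$L_meas[1:6], y = ref$L_ref[1:6]),
               list(x = meas$a_meas[7:12], y = ref$a_ref[7:12]),
               list(x = meas$b_meas[7:12], y = ref$b_ref[7:12]))
  for (k in 1:3) {
    base <- rss_of(co$slope[k], co$intercept[k], sets[[k]]$x, sets[[k]]$y)
    for (ds in c(-1e-3, 1e-3)) for (di in c(-1e-3, 0, 1e-3)) {
      if (ds == 0 && di == 0) next
      expect_gte(rss_of(co$slope[k] + ds, co$intercept[k] + di,
                        sets[[k]]$x, sets[[k]]$y), base)
    }
  }
})

test_that("degenerate measured values are a fit error", {
  ref <- checker_reference()
  meas <- tibble::tibble(L_meas = rep(50, 12), a_meas = ref$a_ref,
                         b_meas = ref$b_ref)
  expect_error(fit_correction(checker_set(meas)), "degenerate")
})

test_that("applying a model transforms pixels and clips L* with a count", {
  lab <- lab_raster(array(c(40, 60, 5, -5, 0, 0), c(2, 1, 3)))
  ident <- fit_correction(checker_set(tibble::tibble(
    L_meas = checker_reference()$L_ref, a_meas = checker_reference()$a_ref,
    b_meas = checker_reference()$b_ref)))
  expect_equal(unclass(apply_correction(lab, ident)), unclass(lab),
               tolerance = 1e-9, ignore_attr = TRUE)

  doubler <- ident
  doubler$coefficients$slope <- c(2, 1, 1)
  out <- apply_correction(lab, doubler)
  expect_equal(unclass(out)[1, 1, 1], 80, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unclass(out)[2, 1, 1], 100, ignore_attr = TRUE) # 120 clipped
  expect_equal(attr(out, "n_clipped"), 1)
})

test_that("fit-then-apply undoes a synthetic distortion end to end", {
  ref <- checker_reference()
  distort <- function(lab) {
    arr <- unclass(lab)
    arr[, , 1] <- pmin((arr[, , 1] - 4) / 0.92, 100)
    arr[, , 2] <- (arr[, , 2] + 1.5) / 1.05
    arr[, , 3] <- (arr[, , 3] - 0.5) / 0.97
    lab_raster(arr)
  }
  true_arr <- array(0, c(12, 4, 3))
  true_arr[, , 1] <- matrix(rep(ref$L_ref, 4), 12)
  true_arr[, , 2] <- matrix(rep(ref$a_ref, 4), 12)
  true_arr[, , 3] <- matrix(rep(ref$b_ref, 4), 12)
  measured <- distort(lab_raster(true_arr))
  regions <- tibble::tibble(patch_id = ref$patch_id, row0 = 1:12, row1 = 1:12,
                            col0 = 1, col1 = 4)
  cs <- sample_checker(measured, regions)
  model <- fit_correction(cs)
  corrected <- apply_correction(measured, model)
  expect_lt(max(abs(unclass(corrected) - true_arr)), 1e-6)
  expect_equal(glance(model)$total_rss, 0, tolerance = 1e-12)
})
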