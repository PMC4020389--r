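test_that("Lilliefors statistic matches a hand-computed 3-point ECDF deviation", {
  # for {-1, 0, 1}: max deviation is Phi(1) - 2/3
  D <- tdch:::lilliefors_statistic(c(-1, 0, 1))
  expect_equal(D, pnorm(1) - 2 / 3, tolerance = 1e-12)
})

test_that("Lilliefors statistic agrees with the nortest implementation", {
  set.seed(40)
  for (n in c(10, 50, 402)) {
    x <- rgamma(n, 2)
    expect_equal(tdch:::lilliefors_statistic(x),
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
})

test_that("Lilliefors p is calibrated under the null and powerful off it", {
  set.seed(8)
  null_sample <- rnorm(500)
  res <- lilliefors_ks(null_sample, n_sim = 2000)
  expect_gt(res$p_value, 0.05)
  expon <- rexp(500)
  res2 <- lilliefors_ks(expon, n_sim = 2000)
  expect_lt(res2$p_value, 0.01)
  expect_false(res2$p_censored)
  # censoring convention: p above 0.2 reported as the 0.2 lower bound
  if (res$p_censored) expect_equal(res$p_value, 0.2)
  expect_error(lilliefors_ks(rep(3, 10)), "constant")
  expect_error(lilliefors_ks(rnorm(3)), "n >= 4")
})

test_that("Shapiro-Wilk wrapper is calibrated and rejects gross non-normality", {
  set.seed(41)
  expect_gt(shapiro_wilk(rnorm(500))$p_value, 0.05)
  expect_lt(shapiro_wilk(rexp(500))$p_value, 0.01)
  sw <- shapiro_wilk(c(1, 2, 3, 5, 4, 7))
  expect_equal(sw$statistic, unname(shapiro.test(c(1, 2, 3, 5, 4, 7))$statistic))
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("Mann-Whitney U: symmetry, the classic 3v3 extreme case, and exactness", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 8) # n*m/2
  expect_equal(same$p_value, 1)

  extreme <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(extreme$statistic, 0)
  expect_equal(extreme$p_value, 0.1) # 2/20 orderings as extreme
  expect_identical(extreme$method, "exact")
})

test_that("exact p equals stats::wilcox.test exact enumeration on tie-free samples", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    ours <- mann_whitney(x, y)
    oracle <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(oracle$statistic))
  }
})

test_that("the approximation is close to exact and handles ties like wilcox.test", {
  set.seed(43)
  worst <- 0
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(7)
    pe <- mann_whitney(x, y)$p_value
    pa <- mann_whitney(x, y, exact_limit = 0)$p_value
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.05)
  # tied data: tie-corrected approximation matches wilcox.test's correction
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  y <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  ours <- mann_whitney(x, y, exact_limit = 0)
  oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-9)
})

test_that("two-sided tests are invariant to swapping group labels", {
  set.seed(44)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$statistic, length(x) * length(y) - b$statistic)
})

test_that("paired t reduces to the one-sample formula on differences", {
  set.seed(45)
  d <- rnorm(18, 0.5, 1)
  res <- paired_t(rep(0, 18), d)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(18)), tolerance = 1e-12)
  expect_equal(res$df, 17)

  expect_equal(paired_t(c(0, 0, 0, 0), c(1, -1, 1, -1))$p_value, 1)
  expect_error(paired_t(1:5, 1:5 + 1), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "equal length")

  # shift identity: paired_t(x, x + c + noise) == one-sample t of (noise + c)
  x <- rnorm(20); noise <- rnorm(20, 0, 0.3)
  r1 <- paired_t(x, x + 0.4 + noise)
  r2 <- t.test(noise + 0.4, mu = 0)
  expect_equal(r1$statistic, unname(r2$statistic), tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p.value, tolerance = 1e-12)
})

test_that("group_compare routes by normality and reports both blocks", {
  co <- generate_cohort(cohort_spec(n_normal = 60, n_sd = 40, seed = 2))
  res <- group_compare(co, n_sim_lilliefors = 500)
  expect_s3_class(res, "group_comparison")
  expect_equal(nrow(res), 7)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  norm <- attr(res, "normality")
  expect_equal(nrow(norm), 7 * 2 * 2) # variable x group x test
  expect_true(all(res$test %in% c("mann_whitney", "welch_t", "error")))

  # constant variable in both groups: isolated error row
  co$V2 <- 0.1
  res2 <- group_compare(co, n_sim_lilliefors = 500)
  expect_identical(res2$test[res2$variable == "V2"], "error")
  expect_false(any(res2$test[res2$variable != "V2"] == "error"))

  expect_error(group_compare(dplyr::mutate(co, group = "x")), "two groups")
})

test_that("paired_compare detects a within-subject shift", {
  co <- generate_cohort(cohort_spec(paired = TRUE, n_paired = 18, seed = 6))
  res <- paired_compare(co)
  expect_equal(nrow(res), 7)
  expect_true(all(res$n == 18))
  expect_true(all(is.finite(res$statistic)))
})
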