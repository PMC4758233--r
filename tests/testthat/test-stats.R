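test_that("Mann-Whitney U matches exact enumeration on the separated case", {
  t <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 0.1)
  expect_equal(t$p_value, oracle_mwu_exact(c(1, 2, 3), c(4, 5, 6)))
})

test_that("U statistics of the two samples always sum to n1*n2", {
  set.seed(41)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:30, 1))
    y <- stats::rnorm(sample(3:30, 1))
    ux <- mann_whitney_u(x, y)$statistic
    uy <- mann_whitney_u(y, x)$statistic
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("identical samples give central U and p near 1", {
  x <- c(1, 2, 3, 4, 5)
  t <- mann_whitney_u(x, x)
  expect_equal(t$statistic, length(x)^2 / 2)
  expect_gte(t$p_value, 0.99)
  tz <- mann_whitney_u(rep(2, 5), rep(2, 8))
  expect_equal(tz$p_value, 1)
  expect_true("zero_variance" %in% tz$flags)
})

test_that("Spearman rho hits the monotone limits and the midrank oracle", {
  x <- 1:10
  expect_equal(spearman_rho(x, x + stats::runif(10))$statistic, 1)
  expect_equal(spearman_rho(x, rev(x))$statistic, -1)
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  expect_equal(spearman_rho(xt, yt)$statistic,
               stats::cor(rank(xt), rank(yt)), tolerance = 1e-12)
  t <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(t$statistic))
  expect_true("zero_rank_variance" %in% t$flags)
})

test_that("Spearman rho is antisymmetric under order reversal", {
  set.seed(44)
  x <- stats::rnorm(25)
  y <- stats::rnorm(25)
  expect_equal(spearman_rho(x, y)$statistic, -spearman_rho(x, -y)$statistic,
               tolerance = 1e-12)
  expect_lte(abs(spearman_rho(x, y)$statistic), 1)
})

test_that("coefficient of variation is SD/mean and scale invariant", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(46)
  x <- stats::rlnorm(50)
  expect_equal(coefficient_of_variation(x), coefficient_of_variation(7 * x),
               tolerance = 1e-12)
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
})

test_that("two-proportion z follows the pooled formula and sign convention", {
  expect_equal(two_proportion_z(5, 10, 50, 100)$statistic, 0)
  t <- two_proportion_z(10, 100, 90, 100)
  expect_equal(t$statistic, oracle_two_prop_z(10, 100, 90, 100),
               tolerance = 1e-12)
  expect_lt(t$statistic, 0)
  expect_lt(t$p_value, 0.001)
  expect_true(is.na(two_proportion_z(0, 10, 0, 10)$statistic))
})

test_that("PCA handles perfect correlation, reconstruction and row order", {
  set.seed(48)
  z <- stats::rnorm(200)
  two <- cbind(a = z, b = 2 * z + 1)
  p2 <- feature_pca(two)
  expect_equal(p2$component_variance_pct[1], 100, tolerance = 1e-8)

  x <- matrix(stats::rnorm(600), ncol = 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  p <- feature_pca(x)
  expect_equal(sum(p$component_variance_pct), 100, tolerance = 1e-6)
  expect_equal(p$loadings %*% t(p$loadings), stats::cor(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(p$loadings) <= 1 + 1e-9))
  p_shuf <- feature_pca(x[sample(nrow(x)), ])
  expect_equal(p$loadings, p_shuf$loadings, tolerance = 1e-9)

  xc <- cbind(x, const = 1)
  expect_error(feature_pca(xc), "const")
})

test_that("PCA variance is near uniform for independent variables", {
  set.seed(49)
  x <- matrix(stats::rnorm(5000 * 5), ncol = 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  p <- feature_pca(x)
  expect_lt(max(abs(p$component_variance_pct - 20)), 3)
})

test_that("histograms use left-closed right-open percent bins from zero", {
  one <- freq_histogram(c(0.01, 0.02, 0.03), 0.1)
  expect_equal(one$frequency_pct, 100)
  expect_equal(one$bin_center, 0.05)
  empty <- freq_histogram(numeric(0), 0.1)
  expect_equal(nrow(empty), 0L)
  four <- freq_histogram(c(0.05, 0.15, 0.25, 0.35), 0.1)
  expect_equal(four$frequency_pct, rep(25, 4))
  # boundary values fall in the right-open bin above them
  edge <- freq_histogram(c(0.1), 0.1)
  expect_equal(edge$bin_center, 0.15)
})
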