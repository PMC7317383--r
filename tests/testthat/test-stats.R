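test_that("concentration regression matches brute-force formulas", {
  conc <- c(0, 1.8, 3.6, 6, 7.2, 9)
  set.seed(3)
  vals <- 1.5 * conc + rnorm(6, 0, 0.5)
  r <- correlate_with_concentration(vals, conc)
  # brute force: normal equations + t test
  n <- 6
  sxx <- sum((conc - mean(conc))^2)
  slope <- sum((conc - mean(conc)) * (vals - mean(vals))) / sxx
  inter <- mean(vals) - slope * mean(conc)
  res <- vals - inter - slope * conc
  r2 <- 1 - sum(res^2) / sum((vals - mean(vals))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p <- 2 * stats::pt(abs(slope / se), n - 2, lower.tail = FALSE)
  expect_equal(r$slope, slope, tolerance = 1e-12)
  expect_equal(r$r_squared, r2, tolerance = 1e-12)
  expect_equal(r$p_value, p, tolerance = 1e-12)

  exact <- correlate_with_concentration(2 * conc, conc)
  expect_equal(exact$r_squared, 1)
  expect_lt(exact$p_value, 1e-6)
  expect_error(correlate_with_concentration(vals, rep(1, 6)), "variance")
  expect_error(correlate_with_concentration(vals[1:2], conc[1:2]), "3")
})

test_that("permuted values rarely correlate with concentration", {
  conc <- c(0, 1.8, 3.6, 6, 7.2, 9)
  set.seed(11)
  vals <- rnorm(6)
  ps <- replicate(100, correlate_with_concentration(sample(vals), conc)$p_value)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("removing an outlier changes R2 as a brute-force refit says", {
  conc <- c(0, 0.26, 0.52, 0.78, 1.04, 1.3)
  vals <- c(5, 2.1, 4.2, 6.1, 8.0, 10.2)   # first point is the outlier
  full <- correlate_with_concentration(vals, conc)
  red <- correlate_with_concentration(vals[-1], conc[-1])
  expect_gt(red$r_squared, full$r_squared)
  expect_equal(red$r_squared,
               summary(stats::lm(vals[-1] ~ conc[-1]))$r.squared,
               tolerance = 1e-12)
})

test_that("rank-sum test matches exact enumeration for small samples", {
  # enumeration oracle: distribution of the rank-sum statistic over all
  # assignments of the pooled ranks
  enum_p <- function(a, b) {
    pooled <- rank(c(a, b))
    W_obs <- sum(pooled[seq_along(a)])
    combs <- utils::combn(length(a) + length(b), length(a))
    Ws <- apply(combs, 2, function(idx) sum(sort(pooled)[idx]))
    mu <- mean(Ws)
    min(1, mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12))
  }
  expect_equal(compare_groups(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(compare_groups(c(1, 2, 3), c(10, 11, 12)),
               enum_p(c(1, 2, 3), c(10, 11, 12)))
  set.seed(8)
  for (i in 1:10) {
    a <- round(rnorm(sample(2:5, 1)), 3)
    b <- round(rnorm(sample(2:5, 1), 1), 3)
    expect_equal(compare_groups(a, b), enum_p(a, b), tolerance = 1e-12)
  }
  expect_gte(compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("rank-sum test has power against a one-sd shift", {
  set.seed(21)
  ps <- replicate(60, compare_groups(rnorm(50), rnorm(50, 1)))
  expect_gte(mean(ps < 0.001), 0.95)
})

test_that("ROI summaries equal brute-force masked statistics", {
  m <- matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 3, 3, 3, 3), 3, 4, byrow = TRUE)
  labs <- matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 0, 0, 0, 0), 3, 4, byrow = TRUE)
  s <- roi_summary(m, labs)
  expect_equal(s$mean, c(1, 2))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$n, c(4L, 4L))
  # checkerboard mask vs direct masked mean
  set.seed(4)
  img <- matrix(rnorm(64), 8, 8)
  cb <- (row(img) + col(img)) %% 2 == 0
  s2 <- roi_summary(img, list(board = cb))
  expect_equal(s2$mean, mean(img[cb]))
  expect_equal(s2$sd, stats::sd(img[cb]))
  expect_error(roi_summary(img, list(none = matrix(FALSE, 8, 8))), "empty")
  expect_error(roi_summary(img, matrix(0L, 2, 2)), "grids")
})
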