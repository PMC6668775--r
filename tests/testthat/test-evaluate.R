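test_that("the inverse transform maps ms to -1000/RT monotonically", {
  expect_equal(inverse_transform(1000), -1)
  expect_equal(inverse_transform(500), -2)
  x <- c(400, 500, 800, 1200)
  expect_true(all(diff(inverse_transform(x)) > 0))
  expect_error(inverse_transform(c(500, 0)), "positive")
  expect_error(inverse_transform(-10), "positive")
})

test_that("standardization gives z-scores with sample sd", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(50, 10, 3)
  expect_equal(mean(standardize(x)), 0)
  expect_equal(sd(standardize(x)), 1)
  expect_equal(standardize(3 * x + 7), standardize(x))
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("scaled linear effects recover known slopes", {
  set.seed(10)
  x <- rnorm(500)
  # identity: slope 1 on standardized scales
  eff <- suppressWarnings(linear_effect(x, standardize(x)))
  expect_equal(eff$beta, 1, tolerance = 1e-6)
  # known effect size recovered at documented precision
  y <- 0.5 * x + rnorm(500, sd = 0.1)
  eff2 <- linear_effect(x, y, "x")
  expect_equal(eff2$beta, 0.5, tolerance = 0.03)
  expect_equal(eff2$predictor, "x")
  expect_equal(eff2$n, 500L)
  expect_error(linear_effect(x, y[-1]), "equal length")
  expect_error(linear_effect(rep(1, 10), rnorm(10)), "constant")
})

test_that("null effects stay null at the documented rate", {
  set.seed(99)
  big_t <- replicate(100, {
    abs(linear_effect(rnorm(500), rnorm(500))$t) >= 3
  })
  expect_gte(mean(!big_t), 0.95)
})

test_that("principal-components regression matches OLS at full rank", {
  set.seed(21)
  X <- matrix(rnorm(200 * 5), 200, 5)
  colnames(X) <- paste0("p", 1:5)
  y <- X %*% runif(5) + rnorm(200, sd = 0.3)
  pcr <- pca_regression(X, y, k = 5)
  ols <- lm(y ~ scale(X))
  expect_equal(pcr$fitted, unname(fitted(ols)), tolerance = 1e-8)
  expect_error(pca_regression(X, y, k = 6), "rank")
  expect_error(pca_regression(X, y[-1], k = 2), "matching rows")
})

test_that("a response built on one component loads only on it", {
  set.seed(22)
  X <- matrix(rnorm(500 * 4), 500, 4)
  X[, 2] <- X[, 1] * 2 + rnorm(500, sd = 0.05)  # dominant direction
  pcr0 <- pca_regression(X, rnorm(500), k = 3)
  scores1 <- scale(X) %*% pcr0$loadings[, 1]
  y <- as.vector(scores1) + rnorm(500, sd = 0.01)
  pcr <- pca_regression(X, y, k = 3)
  expect_gt(abs(pcr$coefficients[1]), 0.9)
  expect_lt(max(abs(pcr$coefficients[-1])), 0.05)
})

test_that("component signs are fixed deterministically", {
  set.seed(23)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rnorm(100)
  a <- pca_regression(X, y, k = 4)
  b <- pca_regression(X, y, k = 4)
  expect_identical(a, b)
  top <- apply(a$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(top > 0))
})

test_that("item-level correlation behaves like Pearson's r", {
  x <- c(1, 2, 5, 9)
  expect_equal(item_correlation(x, 2 * x + 1), 1)
  expect_equal(item_correlation(x, -x), -1)
  set.seed(31)
  n <- 1000
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  expect_equal(item_correlation(a, b), 0.5, tolerance = 0.06)
  expect_error(item_correlation(x, rep(1, 4)), "zero variance")
  expect_error(item_correlation(1:2, 1:2), "at least 3")
})

test_that("estimates are invariant to item order", {
  set.seed(41)
  x <- rnorm(80)
  y <- 0.3 * x + rnorm(80)
  perm <- sample(80)
  expect_equal(linear_effect(x, y)$beta,
               linear_effect(x[perm], y[perm])$beta)
  expect_equal(item_correlation(x, y), item_correlation(x[perm], y[perm]))
})
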