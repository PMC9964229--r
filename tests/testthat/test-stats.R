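test_that("Pearson matrix matches hand formulas and handles degeneracy", {
  x <- c(1, 2, 3, 5)
  y <- 2 * x + 1
  rep1 <- pearson_matrix(cbind(x = x), cbind(y = y))
  expect_equal(rep1$r[1, 1], 1, tolerance = 1e-12)

  set.seed(20)
  a <- rnorm(4)
  b <- rnorm(4)
  rep2 <- pearson_matrix(cbind(a), cbind(b))
  expect_equal(rep2$r[1, 1], hand_pearson(a, b), tolerance = 1e-12)

  # independent columns decorrelate at large n
  set.seed(21)
  u <- rnorm(1000)
  v <- sample(rnorm(1000))
  expect_lt(abs(pearson_matrix(cbind(u), cbind(v))$r[1, 1]), 0.1)

  # p-value agrees with the t transform cross-checked against cor.test
  ct <- cor.test(a, b)
  expect_equal(rep2$p[1, 1], ct$p.value, tolerance = 1e-10)

  # constant column: flagged undefined, not a global failure
  rep3 <- pearson_matrix(cbind(a = a, k = rep(1, 4)), cbind(b = b))
  expect_true(is.na(rep3$r["k", "b"]))
  expect_true(rep3$undefined["k", "b"])
  expect_false(is.na(rep3$r["a", "b"]))

  expect_error(pearson_matrix(cbind(1:2), cbind(1:2)), ">= 3")
})

test_that("self-correlation is symmetric with a unit diagonal", {
  set.seed(22)
  X <- matrix(rnorm(60), 12, 5)
  rep <- pearson_matrix(X)
  expect_equal(diag(rep$r), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rep$r, t(rep$r), tolerance = 1e-12)
})

test_that("correlation banding follows the signed threshold rule", {
  expect_equal(band_correlation(-0.55), "medium negative")
  expect_equal(band_correlation(0), "negligible")
  expect_equal(band_correlation(0.95), "high positive")
  expect_equal(band_correlation(c(0.1, 0.4, 0.7)),
               c("low positive", "medium positive", "high positive"))
  expect_equal(band_correlation(-0.25), "low negative")
  expect_error(band_correlation(1.2), "exceed")
})

test_that("an engineered medium-negative pair is banded as such", {
  # construct y with population correlation -0.55 against x
  set.seed(23)
  n <- 400
  x <- rnorm(n)
  y <- -0.55 * x + sqrt(1 - 0.55^2) * rnorm(n)
  rep <- pearson_matrix(cbind(x), cbind(y))
  expect_equal(rep$band[1, 1], "medium negative")
})

test_that("correlation PCA has orthonormal loadings and faithful scores", {
  set.seed(24)
  X <- matrix(rnorm(80), 16, 5)
  p <- pca_scores(X)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scores uncorrelated across components
  cc <- cov(p$scores)
  expect_equal(cc - diag(diag(cc)), matrix(0, 5, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full reconstruction of the z-scored data
  Z <- scale(X)
  expect_equal(p$scores %*% t(p$loadings), Z, tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading entry positive
  for (k in 1:5) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
})

test_that("PCA degenerates correctly on perfectly correlated variables", {
  x <- c(1, 4, 2, 8, 5)
  p <- pca_scores(cbind(a = x, b = 3 * x + 2))
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  expect_error(pca_scores(matrix(1:4, 2, 2)), ">= 3")
  expect_error(pca_scores(cbind(x, rep(1, 5))), "constant")
})

test_that("clustering merges duplicates first and outliers last", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  h <- hca(X, zscore = FALSE)
  expect_equal(h$height[1], 0)
  first <- hclust_merge_sets(h$merge)[[1]]
  expect_equal(first, c(1, 2))

  expect_error(hca(X, linkage = "centroid"), "unknown linkage")
  expect_error(hca(X, metric = "cosine"), "unknown metric")
  expect_error(hca(X[1, , drop = FALSE]), ">= 2 items")
})

test_that("average linkage reproduces the brute-force merge trace", {
  set.seed(25)
  for (trial in 1:5) {
    X <- matrix(rnorm(10), 5, 2)
    h <- hca(X, zscore = FALSE)
    D <- as.matrix(dist(X))
    oracle <- brute_average_linkage(D)
    expect_equal(h$height, oracle$heights, tolerance = 1e-12)
    expect_equal(hclust_merge_sets(h$merge), oracle$sets)
  }
})

test_that("average-linkage merge heights are monotone on random data", {
  set.seed(26)
  for (trial in 1:20) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    h <- hca(X)
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("heatmap export carries the z-matrix and both leaf orders", {
  set.seed(27)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6),
                                               paste0("v", 1:4)))
  h <- hca(X)
  expect_equal(dim(h$heatmap$matrix), dim(X))
  expect_equal(colMeans(h$heatmap$matrix), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_setequal(h$heatmap$row_order, 1:6)
  expect_setequal(h$heatmap$col_order, 1:4)
})
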