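test_that("entropy impurity matches a direct summation oracle", {
  expect_equal(entropy_impurity(c(1, 0, 0, 0)), 0)
  expect_equal(entropy_impurity(rep(0.25, 4)), log(4))
  expect_equal(entropy_impurity(c(0.5, 0.5)), log(2))

  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- stats::rgamma(k, 1)
    p <- p / sum(p)
    direct <- -sum(ifelse(p > 0, p * log(p), 0))
    expect_equal(entropy_impurity(p), direct, tolerance = 1e-12)
  }
  expect_error(entropy_impurity(c(0.5, 0.6)), "sum to 1")
  expect_error(entropy_impurity(c(1.2, -0.2)), "nonnegative")
})

test_that("discriminant rules solve separated Gaussians and fail on XOR", {
  tr <- make_separated_gaussians(100, seed = 1)
  te <- make_separated_gaussians(100, seed = 2)
  for (fitter in list(fit_fisher, fit_anderson)) {
    fit <- fitter(tr$x, tr$y)
    aer <- 100 * mean(predict(fit, te$x) != te$y)
    expect_lt(aer, 1)
  }

  # same distribution for both classes: chance level
  set.seed(3)
  x0 <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("t1", "t2")))
  y0 <- factor(rep(c("A", "B"), each = 100))
  fit <- fit_fisher(x0, y0)
  x0t <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("t1", "t2")))
  y0t <- factor(rep(c("A", "B"), each = 500))
  aer <- 100 * mean(predict(fit, x0t) != y0t)
  expect_gt(aer, 40)
  expect_lt(aer, 60)

  # XOR is linearly inseparable: both rules stay near chance
  xor_tr <- make_xor_data(100, seed = 4)
  xor_te <- make_xor_data(100, seed = 5)
  for (fitter in list(fit_fisher, fit_anderson)) {
    fit <- fitter(xor_tr$x, xor_tr$y)
    aer <- 100 * mean(predict(fit, xor_te$x) != xor_te$y)
    expect_gt(aer, 35)
  }
})

test_that("discriminant predictions are affine invariant", {
  tr <- make_separated_gaussians(60, sep = 3, seed = 6)
  te <- make_separated_gaussians(60, sep = 3, seed = 7)
  for (fitter in list(fit_fisher, fit_anderson)) {
    f1 <- fitter(tr$x, tr$y)
    f2 <- fitter(tr$x * 2, tr$y)
    expect_identical(predict(f1, te$x), predict(f2, te$x * 2))
  }
})

test_that("anderson's boundary is the Mahalanobis perpendicular bisector", {
  # identity covariance, equal priors: boundary at the midpoint hyperplane
  set.seed(8)
  n <- 4000
  x <- rbind(matrix(rnorm(n, 0, 1), ncol = 2),
             matrix(rnorm(n, 3, 1), ncol = 2))
  colnames(x) <- c("t1", "t2")
  y <- factor(rep(c("A", "B"), each = n / 2))
  fit <- fit_anderson(x, y)
  # points reflected across the empirical midpoint plane swap classes
  mid <- (colMeans(x[y == "A", ]) + colMeans(x[y == "B", ])) / 2
  probe <- rbind(mid - c(0.5, 0.5), mid + c(0.5, 0.5))
  colnames(probe) <- c("t1", "t2")
  pred <- predict(fit, probe)
  expect_equal(as.character(pred), c("A", "B"))
})

test_that("a single split solves a one-trait threshold problem", {
  set.seed(9)
  x <- cbind(t1 = c(runif(50, -1, -0.1), runif(50, 0.1, 1)))
  y <- factor(rep(c("neg", "pos"), each = 50))
  fit <- fit_tree(x, y)
  expect_equal(mean(predict(fit, x) != y), 0)
  # one root split suffices
  expect_lte(sum(fit$fit$frame$var != "<leaf>"), 2)
})

test_that("degenerate bagging equals a single tree; forests solve XOR", {
  ds <- fixture_dataset(n_per_env = 15, seed = 10)
  xy <- phenotype_xy(drop_zero_variance(ds)$data)
  x <- as.matrix(xy$x)
  single <- fit_tree(x, xy$y)
  bag1 <- fit_bagging(x, xy$y, B = 1, bootstrap = FALSE, seed = 1)
  expect_identical(predict(bag1, x), predict(single, x))

  xor_tr <- make_xor_data(100, seed = 11)
  xor_te <- make_xor_data(100, seed = 12)
  rf <- fit_random_forest(xor_tr$x, xor_tr$y, n_trees = 200, seed = 1)
  aer_rf <- 100 * mean(predict(rf, xor_te$x) != xor_te$y)
  expect_lt(aer_rf, 10)
  fis <- fit_fisher(xor_tr$x, xor_tr$y)
  aer_f <- 100 * mean(predict(fis, xor_te$x) != xor_te$y)
  expect_gt(aer_f, 35)
})

test_that("ensembles are deterministic given a seed and validate config", {
  ds <- fixture_dataset(n_per_env = 10, seed = 13)
  xy <- phenotype_xy(drop_zero_variance(ds)$data)
  x <- as.matrix(xy$x)
  b1 <- fit_bagging(x, xy$y, B = 25, seed = 5)
  b2 <- fit_bagging(x, xy$y, B = 25, seed = 5)
  expect_identical(predict(b1, x), predict(b2, x))
  r1 <- fit_random_forest(x, xy$y, n_trees = 50, seed = 5)
  r2 <- fit_random_forest(x, xy$y, n_trees = 50, seed = 5)
  expect_identical(predict(r1, x), predict(r2, x))

  expect_error(fit_bagging(x, xy$y, B = 0), "at least 1")
  expect_error(fit_boosting(x, xy$y, depth = 0), "depth")
  expect_error(fit_boosting(x, xy$y, shrinkage = 1.5), "shrinkage")
})

test_that("boosting learns the fixture classes and interpolates in-sample", {
  ds <- fixture_dataset(n_per_env = 15, seed = 14)
  xy <- phenotype_xy(drop_zero_variance(ds)$data)
  x <- as.matrix(xy$x)
  fit <- fit_boosting(x, xy$y, n_trees = 300, seed = 1)
  expect_lt(mean(predict(fit, x) != xy$y), 0.05)
  # predictions restricted to training labels
  expect_true(all(predict(fit, x) %in% levels(xy$y)))
})

test_that("supervised methods interpolate separable training data", {
  d <- make_four_clusters(30, seed = 15)
  for (fitter in list(fit_tree,
                      function(x, y) fit_bagging(x, y, B = 50),
                      function(x, y) fit_random_forest(x, y, n_trees = 100))) {
    fit <- fitter(d$x, d$y)
    expect_equal(mean(predict(fit, d$x) != d$y), 0)
  }
})

test_that("bagging does not hurt relative to a single tree on average", {
  ds <- fixture_dataset(n_per_env = 22, seed = 1)
  xy <- phenotype_xy(drop_zero_variance(ds)$data)
  x <- as.matrix(xy$x)
  tree_aer <- bag_aer <- numeric(20)
  for (s in 1:20) {
    fp <- make_fold_plan(xy$y, k = 4, n_repeats = 1, seed = 100 + s)
    te <- which(fp$assignment[, 1] == 1)
    tr <- setdiff(seq_len(nrow(x)), te)
    single <- fit_tree(x[tr, ], xy$y[tr])
    bag <- fit_bagging(x[tr, ], xy$y[tr], B = 500, seed = s)
    tree_aer[s] <- 100 * mean(predict(single, x[te, ]) != xy$y[te])
    bag_aer[s] <- 100 * mean(predict(bag, x[te, ]) != xy$y[te])
  }
  expect_lte(mean(bag_aer), mean(tree_aer))
})
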