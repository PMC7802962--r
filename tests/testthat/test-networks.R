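test_that("nguyen-widrow initialization has the prescribed geometry", {
  init <- nguyen_widrow_init(4, 12, seed = 1)
  magnitude <- 0.7 * 12^(1 / 4)        # independent recomputation
  expect_equal(unname(sqrt(colSums(init$W^2))), rep(magnitude, 12))
  expect_equal(sort(abs(init$b))[c(1, 12)],
               magnitude * c(min(abs(seq(-1, 1, length.out = 12))), 1))

  # determinism and the single-unit magnitude
  expect_identical(nguyen_widrow_init(7, 3, seed = 9),
                   nguyen_widrow_init(7, 3, seed = 9))
  one <- nguyen_widrow_init(5, 1, seed = 2)
  expect_equal(unname(sqrt(sum(one$W^2))), 0.7)   # H = 1 -> H^(1/I) = 1
  expect_equal(one$b, 0)
  expect_error(nguyen_widrow_init(0, 3, seed = 1), ">= 1")
})

test_that("the MLP solves XOR and linearly separable benchmarks", {
  xor_tr <- make_xor_data(80, seed = 1)
  xor_te <- make_xor_data(80, seed = 2)
  fit <- fit_mlp(xor_tr$x, xor_tr$y, hidden = list(c(8, 5)), epochs = 1500,
                 lambda = 1e-3, seed = 3)
  aer <- 100 * mean(predict(fit, xor_te$x) != xor_te$y)
  expect_lt(aer, 5)

  sep_tr <- make_separated_gaussians(60, p = 2, sep = 10, seed = 3)
  sep_te <- make_separated_gaussians(60, p = 2, sep = 10, seed = 4)
  mm <- minmax_normalize(sep_tr$x, sep_te$x)
  fit <- fit_mlp(mm$train, sep_tr$y, hidden = list(c(6, 5)), epochs = 800,
                 lambda = 1e-3, seed = 5)
  expect_lt(100 * mean(predict(fit, mm$test) != sep_te$y), 1)

  # output scores: one column per class, argmax-decodable
  sc <- predict(fit, mm$test, type = "score")
  expect_equal(dim(sc), c(nrow(mm$test), nlevels(sep_tr$y)))
  expect_identical(colnames(sc), levels(sep_tr$y))

  expect_error(fit_mlp(mm$train * 100, sep_tr$y, hidden = list(c(5, 5)),
                       epochs = 10), "unnormalized")
})

test_that("MLP fitting is deterministic given a seed", {
  d <- make_xor_data(40, seed = 6)
  f1 <- fit_mlp(d$x, d$y, hidden = list(c(6, 5)), epochs = 300,
                lambda = 1e-3, seed = 7)
  f2 <- fit_mlp(d$x, d$y, hidden = list(c(6, 5)), epochs = 300,
                lambda = 1e-3, seed = 7)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W3, f2$W3)
})

test_that("the RBF network handles separable clusters and XOR", {
  d_tr <- make_four_clusters(40, seed = 8)
  d_te <- make_four_clusters(40, seed = 9)
  fit <- fit_rbf(d_tr$x, d_tr$y, neurons = c(10, 20), radius = c(5, 10),
                 seed = 1)
  expect_lt(100 * mean(predict(fit, d_te$x) != d_te$y), 1)

  xor_tr <- make_xor_data(80, seed = 10)
  xor_te <- make_xor_data(80, seed = 11)
  fit <- fit_rbf(xor_tr$x, xor_tr$y, neurons = c(10, 20, 30),
                 radius = c(5, 10, 15), K = 4, seed = 2)
  expect_lt(100 * mean(predict(fit, xor_te$x) != xor_te$y), 10)
})

test_that("in the large-radius limit the RBF degenerates gracefully", {
  # radius -> inf: all hidden activations -> 1, so the design matrix is a
  # constant feature block and predictions collapse to a single class
  d <- make_four_clusters(20, seed = 12)
  Phi <- coffeeDiscrim:::rbf_design(d$x, d$x[1:5, ], 1e8)
  expect_true(all(abs(Phi[, -1] - 1) < 1e-10))
  fit <- fit_rbf(d$x, d$y, neurons = 10, radius = 1e8, seed = 3)
  expect_equal(length(unique(predict(fit, d$x))), 1)
})

test_that("RBF centers: K-means stage plus farthest-point augmentation", {
  d <- make_four_clusters(30, seed = 13)
  centers <- coffeeDiscrim:::rbf_centers(d$x, 4, 12, seed = 4)
  expect_equal(dim(centers), c(12, 2))
  # the first 4 rows are cluster centers, near the true corners
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d2 <- outer(rowSums(centers[1:4, ]^2), rowSums(corners^2), "+") -
    2 * centers[1:4, ] %*% t(corners)
  expect_lt(max(apply(d2, 1, min)), 0.05)
  expect_error(coffeeDiscrim:::rbf_centers(d$x[1:3, ], 4, 10, 1), "exceeds")
})

test_that("the Kohonen map recovers separable clusters but not subtle ones", {
  d <- make_four_clusters(30, seed = 14)
  ks <- fit_ksom(d$x, neurons = 4, iterations = 1500, seed = 1, labels = d$y)
  # each unit captures exactly one environment: permutation cross-tab
  tab <- as.matrix(ks$crosstab)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # identical observations all map to a single unit
  x_const <- matrix(1, 20, 3, dimnames = list(NULL, paste0("t", 1:3)))
  ks2 <- fit_ksom(x_const, neurons = 4, iterations = 100, seed = 2)
  expect_equal(length(unique(ks2$assignment)), 1)

  # fixture-generated data: clusters do NOT align with environments
  # (the two Araponga environments are nearly indistinguishable unsupervised)
  ds <- fixture_dataset(n_per_env = 22, seed = 15)
  xy <- phenotype_xy(drop_zero_variance(ds)$data)
  ks3 <- fit_ksom(as.matrix(xy$x), neurons = 4, iterations = 1000, seed = 3,
                  labels = xy$y)
  tab3 <- as.matrix(ks3$crosstab)
  is_perm <- all(rowSums(tab3 > 0) == 1) && all(colSums(tab3 > 0) == 1)
  expect_false(is_perm)
  expect_error(fit_ksom(d$x, iterations = 0), "iterations")
})
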