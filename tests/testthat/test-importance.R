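train_small_net <- function(method = "mlp", seed = 1) {
  d <- make_four_signal_data(n_per_class = 25, n_noise = 6, seed = seed)
  xy <- phenotype_xy(d)
  mm <- minmax_normalize(as.matrix(xy$x))
  fit <- if (method == "mlp") {
    fit_mlp(mm$train, xy$y, hidden = list(c(8, 6)), epochs = 800,
            lambda = 1e-3, seed = seed)
  } else {
    fit_rbf(mm$train, xy$y, neurons = 12, radius = 5, seed = seed)
  }
  list(fit = fit, x = mm$train, y = xy$y, ranges = mm$ranges, raw = xy$x)
}

test_that("zeroing a dead input changes nothing; zeroing all collapses", {
  s <- train_small_net("mlp")
  fit <- s$fit

  # trait whose first-layer weights are already all zero
  dead <- zero_input_weights(fit, "noise1")
  expect_equal(zeroing_delta(dead, s$x, s$y, "noise1"), 0)

  # purity: the original model is untouched by the techniques
  w1_before <- fit$W1
  invisible(zeroing_delta(fit, s$x, s$y, "signal1"))
  invisible(randomization_delta(fit, s$x, s$y, "signal2", seed = 1))
  expect_identical(fit$W1, w1_before)

  # zeroing every trait: the forward pass is bias-driven and constant
  all_zero <- fit
  for (tr in fit$features) all_zero <- zero_input_weights(all_zero, tr)
  pred <- predict(all_zero, s$x)
  expect_equal(length(unique(pred)), 1)
  # its AER is exactly that constant class's error
  expect_equal(coffeeDiscrim:::model_aer(all_zero, s$x, s$y),
               100 * mean(pred != s$y))

  expect_error(zero_input_weights(fit, "nope"), "unknown trait")
  expect_error(zero_input_weights(fit, 99), "out of range")
  tree_fit <- fit_tree(s$x, s$y)
  expect_error(zero_input_weights(tree_fit, 1), "unsupported")
})

test_that("signal traits dominate noise traits on held-out data", {
  d_te <- make_four_signal_data(n_per_class = 25, n_noise = 6, seed = 99)
  xy_te <- phenotype_xy(d_te)
  for (method in c("mlp", "rbf")) {
    s <- train_small_net(method)
    x_te <- minmax_normalize(s$raw, as.matrix(xy_te$x))$test
    sig_z <- vapply(paste0("signal", 1:4),
                    function(tr) zeroing_delta(s$fit, x_te, xy_te$y, tr),
                    numeric(1))
    noise_z <- vapply(paste0("noise", 1:6),
                      function(tr) zeroing_delta(s$fit, x_te, xy_te$y, tr),
                      numeric(1))
    if (method == "mlp") {
      # zeroing an MLP input removes the trait outright: clear dominance
      expect_gt(min(sig_z), max(noise_z))
    } else {
      # RBF center-zeroing perturbs flat kernels only weakly; it must never
      # rank a noise trait above a signal trait
      expect_gte(min(sig_z), max(noise_z))
    }
    sig_r <- vapply(paste0("signal", 1:4),
                    function(tr) randomization_delta(s$fit, x_te, xy_te$y, tr,
                                                     seed = 3),
                    numeric(1))
    expect_gt(min(sig_r), 0)
  }
})

test_that("randomizing a constant trait is an exact no-op", {
  s <- train_small_net("mlp")
  x2 <- cbind(s$x, flat = 0.5)
  fit <- fit_mlp(x2, s$y, hidden = list(c(8, 6)), epochs = 300,
                 lambda = 1e-3, seed = 2)
  expect_identical(randomization_delta(fit, x2, s$y, "flat", seed = 5), 0)
  expect_error(randomization_delta(fit, x2[1, , drop = FALSE], s$y[1],
                                   "flat"), "2 test rows")
})

test_that("pure-noise permutation deltas average to ~0", {
  s <- train_small_net("rbf")
  deltas <- vapply(1:50, function(sd) {
    randomization_delta(s$fit, s$x, s$y, "noise3", seed = sd)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 1)
})

test_that("relative importance normalizes, floors, and is scale-free", {
  d <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  d[1, ] <- c(1, 1, 0.5, 0.5)
  ri <- relative_importance(d)
  expect_equal(ri$ri, c(100, 0, 0))

  # equal positive sums spread evenly
  d31 <- matrix(1, 31, 3, dimnames = list(paste0("t", 1:31), NULL))
  expect_equal(relative_importance(d31)$ri, rep(100 / 31, 31))

  # random nonnegative matrices: direct summation oracle, sums to 100
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(stats::rexp(8 * 5), 8, 5,
                dimnames = list(paste0("t", 1:8), NULL))
    ri <- relative_importance(m)
    expect_equal(sum(ri$ri), 100, tolerance = 1e-9)
    expect_equal(ri$ri, unname(100 * rowSums(m) / sum(rowSums(m))),
                 tolerance = 1e-12)
    # scale freedom
    expect_equal(relative_importance(3.7 * m)$ri, ri$ri, tolerance = 1e-12)
  }

  # negative sums floored before normalization, raw sums kept
  d <- matrix(c(2, -1), 2, 1, dimnames = list(c("up", "down"), NULL))
  ri <- relative_importance(d)
  expect_equal(ri$ri, c(100, 0))
  expect_equal(ri$delta_sum, c(2, -1))

  expect_error(relative_importance(matrix(-1, 2, 2)), "no trait degrades")
})

test_that("cutoff selection averages across the four quadrants", {
  mk <- function(...) {
    v <- c(...)
    data.frame(trait = paste0("t", seq_along(v)), delta_sum = v, ri = v)
  }
  quads <- list(mk(20, 40, 5), mk(20, 0, 5), mk(20, 0, 5), mk(20, 0, 5))
  expect_equal(select_important(quads, cutoff = 15), "t1")  # t2 mean 10 < 15
  expect_error(select_important(list(mk(1, 2), mk(1, 2, 3))), "mismatched")
})
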