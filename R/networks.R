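# Multilayer perceptron and radial basis function classifiers. Both expect
# inputs normalized to [0, 1] (see minmax_normalize) and expose their
# first-layer weights addressable by input trait, which the weight-zeroing
# importance technique requires.

#' Nguyen-Widrow layer initialization
#'
#' Draws random direction weights and rescales each hidden unit's incoming
#' weight vector to the magnitude \eqn{0.7 \cdot H^{1/I}} (`H` hidden units,
#' `I` inputs), then spaces the biases uniformly across the active input
#' region so the units partition it into small intervals. Deterministic
#' given the seed.
#'
#' @param n_in Number of inputs to the layer.
#' @param n_hidden Number of units in the layer.
#' @param seed Integer seed.
#' @return List with `W` (`n_in x n_hidden` weights) and `b` (length
#'   `n_hidden` biases).
#' @examples
#' init <- nguyen_widrow_init(3, 5, seed = 1)
#' sqrt(colSums(init$W^2))  # all equal 0.7 * 5^(1/3)
#' @export
nguyen_widrow_init <- function(n_in, n_hidden, seed) {
  if (n_in < 1 || n_hidden < 1) stop("layer dimensions must be >= 1")
  set.seed(seed)
  magnitude <- 0.7 * n_hidden^(1 / n_in)
  W <- matrix(stats::runif(n_in * n_hidden, -0.5, 0.5), n_in, n_hidden)
  nrm <- sqrt(colSums(W^2))
  while (any(nrm == 0)) {     # degenerate zero-norm draw: redraw that unit
    z <- which(nrm == 0)
    W[, z] <- stats::runif(n_in * length(z), -0.5, 0.5)
    nrm <- sqrt(colSums(W^2))
  }
  W <- sweep(W, 2, magnitude / nrm, "*")
  b <- if (n_hidden == 1) 0 else {
    magnitude * seq(-1, 1, length.out = n_hidden) * sign(W[1, ])
  }
  list(W = W, b = as.numeric(b))
}

check_normalized <- function(x) {
  if (min(x) < -1 || max(x) > 2) {
    stop("inputs appear unnormalized (values far outside [0, 1]); ",
         "apply minmax_normalize() to the training data first")
  }
}

mlp_forward <- function(w, x) {
  a1 <- tanh(sweep(x %*% w$W1, 2, w$b1, "+"))
  a2 <- tanh(sweep(a1 %*% w$W2, 2, w$b2, "+"))
  out <- sweep(a2 %*% w$W3, 2, w$b3, "+")
  list(a1 = a1, a2 = a2, out = out)
}

mlp_loss_grad <- function(w, x, t, lambda) {
  n <- nrow(x)
  f <- mlp_forward(w, x)
  err <- f$out - t
  loss <- sum(err^2) / (2 * n) +
    lambda / 2 * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2))
  d3 <- err / n
  gW3 <- crossprod(f$a2, d3) + lambda * w$W3
  gb3 <- colSums(d3)
  d2 <- (d3 %*% t(w$W3)) * (1 - f$a2^2)
  gW2 <- crossprod(f$a1, d2) + lambda * w$W2
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(w$W2)) * (1 - f$a1^2)
  gW1 <- crossprod(x, d1) + lambda * w$W1
  gb1 <- colSums(d1)
  list(loss = loss,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3))
}

mlp_train_one <- function(x, t, hidden, epochs, lambda, lr0, seed) {
  n_in <- ncol(x)
  K <- ncol(t)
  i1 <- nguyen_widrow_init(n_in, hidden[1], child_seed(seed, 1L))
  i2 <- nguyen_widrow_init(hidden[1], hidden[2], child_seed(seed, 2L))
  i3 <- nguyen_widrow_init(hidden[2], K, child_seed(seed, 3L))
  w <- list(W1 = i1$W, b1 = i1$b, W2 = i2$W, b2 = i2$b, W3 = i3$W, b3 = i3$b)
  vel <- lapply(w, function(z) z * 0)
  lr <- lr0
  mom <- 0.9
  cur <- mlp_loss_grad(w, x, t, lambda)
  for (ep in seq_len(epochs)) {
    vel <- mapply(function(v, g) mom * v - lr * g, vel, cur$grad,
                  SIMPLIFY = FALSE)
    cand <- mapply(`+`, w, vel, SIMPLIFY = FALSE)
    nxt <- mlp_loss_grad(cand, x, t, lambda)
    if (!is.finite(nxt$loss)) stop("non-finite loss during MLP training")
    if (nxt$loss <= cur$loss * 1.0001) {
      # accept the step; gently grow the learning rate (bold driver)
      w <- cand
      cur <- nxt
      lr <- min(lr * 1.02, 1)
    } else {
      # reject: halve the rate and damp the momentum buffer
      lr <- lr * 0.5
      vel <- lapply(vel, function(v) v * 0.5)
      if (lr < 1e-12) break
    }
  }
  list(weights = w, loss = cur$loss)
}

#' Multilayer perceptron classifier
#'
#' Two hidden layers with hyperbolic tangent sigmoid activation, linear
#' output units scored against one-hot targets, Nguyen-Widrow weight
#' initialization, and full-batch gradient descent with momentum, an
#' adaptive (bold-driver) step size, and an L2 weight penalty. When more
#' than one `(n1, n2)` architecture is supplied, each candidate is trained
#' on a stratified 75% inner split of the training fold and the architecture
#' with the lowest inner-validation apparent error rate is retrained on the
#' full fold (ties go to the smaller network).
#'
#' @param x Matrix/data frame of traits normalized to \[0, 1\].
#' @param y Class labels (factor).
#' @param hidden List of `c(n1, n2)` hidden-layer size candidates, each
#'   within 5-40 units.
#' @param epochs Training epochs per candidate (default 5000).
#' @param lambda L2 weight penalty candidates; with more than one value the
#'   penalty joins the architecture in the inner-validation grid, playing
#'   the role that adaptive (Bayesian) regularization plays in
#'   Levenberg-Marquardt training.
#' @param lr0 Initial learning rate (default 0.01).
#' @param inner_frac Fraction of the fold used for inner training when
#'   selecting a candidate (default 0.75).
#' @param seed Integer seed.
#' @return A `discrim_mlp` model; its `W1` input weights are addressable by
#'   trait name (rows), which the zeroing importance technique uses.
#' @export
fit_mlp <- function(x, y, hidden = list(c(20, 10)),
                    epochs = 5000, lambda = c(0.003, 0.01, 0.03),
                    lr0 = 0.01, inner_frac = 0.75, seed = 1) {
  d <- check_xy(x, y)
  check_normalized(d$x)
  if (is.numeric(hidden)) hidden <- list(hidden)
  t_full <- one_hot(d$y)

  cand <- expand.grid(h = seq_along(hidden), lam = lambda)
  pick <- 1L
  if (nrow(cand) > 1) {
    tr_idx <- stratified_split(d$y, inner_frac, child_seed(seed, 21L))
    va_idx <- setdiff(seq_len(nrow(d$x)), tr_idx)
    inner_aer <- vapply(seq_len(nrow(cand)), function(ci) {
      fit <- mlp_train_one(d$x[tr_idx, , drop = FALSE],
                           t_full[tr_idx, , drop = FALSE],
                           hidden[[cand$h[ci]]], epochs, cand$lam[ci], lr0,
                           child_seed(seed, 22L, cand$h[ci]))
      pred <- decode_scores(mlp_forward(fit$weights,
                                        d$x[va_idx, , drop = FALSE])$out,
                            levels(d$y))
      mean(pred != d$y[va_idx])
    }, numeric(1))
    sizes <- vapply(cand$h, function(h) sum(hidden[[h]]), numeric(1))
    # ties: smaller network first, then the stronger penalty
    pick <- order(inner_aer, sizes, -cand$lam)[1]
  }
  best <- hidden[[cand$h[pick]]]
  best_lam <- cand$lam[pick]
  fit <- mlp_train_one(d$x, t_full, best, epochs, best_lam, lr0,
                       child_seed(seed, 23L))
  new_model("mlp", c(fit$weights,
                     list(hidden = best, lambda = best_lam, loss = fit$loss,
                          levels = levels(d$y), features = colnames(d$x))))
}

#' @export
predict.discrim_mlp <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  m <- prep_newdata(object, newdata)
  w <- object[c("W1", "b1", "W2", "b2", "W3", "b3")]
  out <- mlp_forward(w, m)$out
  colnames(out) <- object$levels
  if (type == "score") return(out)
  decode_scores(out, object$levels)
}

# ---- Radial basis function network ----------------------------------------

rbf_design <- function(x, centers, radius) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  cbind(1, exp(-d2 / (2 * radius^2)))
}

rbf_centers <- function(x, K, n_neurons, seed) {
  if (K > nrow(x)) stop("K exceeds the number of observations")
  for (attempt in 1:5) {
    km <- tryCatch({
      set.seed(child_seed(seed, 31L, attempt))
      stats::kmeans(x, centers = K, nstart = 5, iter.max = 100)
    }, error = function(e) NULL)       # empty-cluster failures: re-seed
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means stage failed repeatedly")
  centers <- km$centers
  extra <- n_neurons - nrow(centers)
  if (extra > 0) {
    # deterministic augmentation: training points farthest from their center
    dists <- sqrt(rowSums((x - centers[km$cluster, , drop = FALSE])^2))
    ord <- order(-dists, seq_along(dists))
    centers <- rbind(centers, x[ord[seq_len(min(extra, nrow(x)))], ,
                                drop = FALSE])
  }
  unname(centers[seq_len(min(n_neurons, nrow(centers))), , drop = FALSE])
}

rbf_solve <- function(Phi, t, lambda) {
  p <- ncol(Phi)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0                      # intercept unpenalized
  qr.solve(crossprod(Phi) + pen, crossprod(Phi, t), tol = 1e-300)
}

rbf_fit_one <- function(x, t, K, n_neurons, radius, lambda, seed) {
  centers <- rbf_centers(x, K, n_neurons, seed)
  Phi <- rbf_design(x, centers, radius)
  W <- rbf_solve(Phi, t, lambda)
  list(centers = centers, radius = radius, W = W)
}

#' Radial basis function network classifier
#'
#' Hybrid two-stage classifier: an unsupervised first stage places Gaussian
#' hidden units \eqn{\phi(x) = \exp(-\|x - c\|^2 / 2r^2)} at K-means
#' centers (K = number of environments; additional units up to the
#' configured neuron count sit at the training points farthest from their
#' cluster center), and a supervised second stage fits linear output
#' weights to one-hot targets by regularized least squares. The neuron
#' count and radius are chosen over a grid by inner-validation apparent
#' error rate (ties to the smaller network).
#'
#' @inheritParams fit_mlp
#' @param neurons Hidden-unit count candidates within 10-50.
#' @param radius Gaussian radius candidates within 5-15 (on the scale of the
#'   normalized inputs).
#' @param K First-stage cluster count (default 4, the number of
#'   environments).
#' @param inner_splits Number of stratified inner splits averaged when
#'   selecting the architecture (default 3; the output stage is closed-form,
#'   so repeated refits are cheap).
#' @param lambda Ridge penalty of the output stage.
#' @return A `discrim_rbf` model; its hidden-unit `centers` are addressable
#'   by trait (columns), which the zeroing importance technique uses.
#' @export
fit_rbf <- function(x, y, neurons = seq(10, 50, by = 10),
                    radius = c(5, 10, 15),
                    K = 4, lambda = 1e-4, inner_frac = 0.75,
                    inner_splits = 3, seed = 1) {
  d <- check_xy(x, y)
  check_normalized(d$x)
  t_full <- one_hot(d$y)
  grid <- expand.grid(n = neurons, r = radius)

  pick <- 1L
  if (nrow(grid) > 1) {
    # the refit is closed-form, so the selection AER is averaged over a few
    # stratified inner splits to damp the noise of a single small split
    inner_aer <- matrix(NA_real_, nrow(grid), inner_splits)
    for (s in seq_len(inner_splits)) {
      tr_idx <- stratified_split(d$y, inner_frac, child_seed(seed, 41L, s))
      va_idx <- setdiff(seq_len(nrow(d$x)), tr_idx)
      inner_aer[, s] <- vapply(seq_len(nrow(grid)), function(g) {
        fit <- rbf_fit_one(d$x[tr_idx, , drop = FALSE],
                           t_full[tr_idx, , drop = FALSE],
                           min(K, length(tr_idx)), grid$n[g], grid$r[g],
                           lambda, child_seed(seed, 42L, s, g))
        sc <- rbf_design(d$x[va_idx, , drop = FALSE], fit$centers,
                         fit$radius) %*% fit$W
        mean(decode_scores(sc, levels(d$y)) != d$y[va_idx])
      }, numeric(1))
    }
    # ties: fewer neurons, then the smoother (larger-radius) unit
    pick <- order(rowMeans(inner_aer), grid$n, -grid$r)[1]
  }
  fit <- rbf_fit_one(d$x, t_full, K, grid$n[pick], grid$r[pick], lambda,
                     child_seed(seed, 43L))
  colnames(fit$centers) <- colnames(d$x)
  new_model("rbf", list(centers = fit$centers, radius = fit$radius,
                        W = fit$W, K = K, levels = levels(d$y),
                        features = colnames(d$x)))
}

#' @export
predict.discrim_rbf <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  m <- prep_newdata(object, newdata)
  sc <- rbf_design(m, object$centers, object$radius) %*% object$W
  colnames(sc) <- object$levels
  if (type == "score") return(sc)
  decode_scores(sc, object$levels)
}
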