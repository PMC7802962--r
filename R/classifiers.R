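# Supervised classifiers behind a common fit/predict contract. Every fitter
# returns an object inheriting from "discrim_model" whose predict() method
# maps a matrix/data frame of traits (training column order) to a factor of
# environment labels restricted to the training levels.

#' Entropy impurity of a class-proportion vector
#'
#' \eqn{i_E(p) = -\sum_j p_j \log p_j} in nats; zero proportions contribute
#' zero by convention. This is the split criterion optimized by the
#' classification tree (deviance-based splitting is entropy splitting up to
#' the constant factor \eqn{2n}). Zero for a pure node; maximal
#' (\eqn{\log J}) when classes are uniform.
#'
#' @param p Numeric vector of nonnegative class proportions summing to 1.
#' @param tol Tolerance on the sum-to-one check.
#' @return Nonnegative entropy in nats.
#' @examples
#' entropy_impurity(c(1, 0, 0, 0))       # 0
#' entropy_impurity(rep(0.25, 4))        # log(4)
#' @export
entropy_impurity <- function(p, tol = 1e-8) {
  if (any(p < -tol)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > tol) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

check_xy <- function(x, y) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("x and y have mismatched lengths")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  list(x = x, y = y)
}

new_model <- function(method, fields) {
  structure(c(list(method = method), fields),
            class = c(paste0("discrim_", method), "discrim_model"))
}

prep_newdata <- function(object, newdata) {
  m <- as_feature_matrix(newdata)
  if (!is.null(object$features)) {
    if (!is.null(colnames(m)) && all(object$features %in% colnames(m))) {
      m <- m[, object$features, drop = FALSE]
    } else if (ncol(m) != length(object$features)) {
      stop("newdata does not match the ", length(object$features),
           " training traits")
    }
  }
  m
}

#' @export
print.discrim_model <- function(x, ...) {
  cat("Fitted", x$method, "classifier;",
      length(x$levels), "classes,", length(x$features), "traits\n")
  invisible(x)
}

# ---- Fisher canonical discriminant ----------------------------------------

#' Fisher linear discriminant classifier
#'
#' Canonical discriminant axes from the eigen-decomposition of
#' \eqn{W^{-1}B} (within- vs between-class scatter); a new observation is
#' assigned to the class whose centroid is nearest in the canonical space.
#' The rule is invariant to affine rescaling of the inputs.
#'
#' @param x Matrix or data frame of traits.
#' @param y Class labels (factor).
#' @return A `discrim_fisher` model.
#' @export
fit_fisher <- function(x, y) {
  d <- check_xy(x, y)
  p <- ncol(d$x)
  n <- nrow(d$x)
  K <- nlevels(d$y)
  mu <- t(vapply(levels(d$y),
                 function(l) colMeans(d$x[d$y == l, , drop = FALSE]),
                 numeric(p)))
  W <- matrix(0, p, p)
  for (l in levels(d$y)) {
    xl <- d$x[d$y == l, , drop = FALSE]
    if (nrow(xl) > 1) W <- W + crossprod(sweep(xl, 2, colMeans(xl)))
  }
  W <- W / (n - K)
  nl <- as.numeric(table(d$y))
  mbar <- colSums(mu * nl) / n
  B <- crossprod(sweep(mu, 2, mbar) * sqrt(nl)) / (n - 1)

  # whiten the within scatter (ridge only if numerically singular), then a
  # symmetric eigenproblem gives the canonical axes with unit pooled
  # within-class variance
  L <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(L)) {
    L <- chol(W + diag(1e-8 * mean(diag(W)) + 1e-12, p))
  }
  M <- backsolve(L, t(backsolve(L, B, transpose = TRUE)), transpose = TRUE)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(p, K - 1)
  scaling <- backsolve(L, eig$vectors[, seq_len(n_axes), drop = FALSE])
  dimnames(scaling) <- list(colnames(d$x), paste0("LD", seq_len(n_axes)))

  proj <- d$x %*% scaling
  centroids <- apply(proj, 2, function(col) tapply(col, d$y, mean))
  centroids <- matrix(centroids, nrow = K,
                      dimnames = list(levels(d$y), colnames(scaling)))
  new_model("fisher", list(scaling = scaling, centroids = centroids,
                           eigenvalues = eig$values[seq_len(n_axes)],
                           levels = levels(d$y), features = colnames(d$x)))
}

#' @export
predict.discrim_fisher <- function(object, newdata, ...) {
  m <- prep_newdata(object, newdata)
  proj <- m[, rownames(object$scaling), drop = FALSE] %*% object$scaling
  d2 <- outer(rowSums(proj^2), rowSums(object$centroids^2), "+") -
    2 * proj %*% t(object$centroids)
  decode_scores(-d2, object$levels)
}

# ---- Anderson linear classification rule ----------------------------------

#' Anderson linear classification functions
#'
#' The multivariate-normal equal-covariance classification rule: linear
#' scores \eqn{s_l(x) = \mu_l' \Sigma^{-1} x - \frac{1}{2}\mu_l' \Sigma^{-1}
#' \mu_l + \log \pi_l} with pooled within-class covariance and priors
#' proportional to training class frequencies; the class with the largest
#' score is assigned (ties resolved toward the lowest class index). A small
#' ridge is added to the pooled covariance only if it is numerically
#' singular.
#'
#' @inheritParams fit_fisher
#' @return A `discrim_anderson` model.
#' @export
fit_anderson <- function(x, y) {
  d <- check_xy(x, y)
  p <- ncol(d$x)
  n <- nrow(d$x)
  K <- nlevels(d$y)
  mu <- t(vapply(levels(d$y),
                 function(l) colMeans(d$x[d$y == l, , drop = FALSE]),
                 numeric(p)))
  S <- matrix(0, p, p)
  for (l in levels(d$y)) {
    xl <- d$x[d$y == l, , drop = FALSE]
    if (nrow(xl) > 1) S <- S + crossprod(sweep(xl, 2, colMeans(xl)))
  }
  S <- S / (n - K)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    ridge <- 1e-6 * mean(diag(S))
    Sinv <- solve(S + diag(ridge, p))
  }
  A <- Sinv %*% t(mu)                       # p x K coefficient matrix
  priors <- as.numeric(table(d$y)) / n
  const <- -0.5 * colSums(t(mu) * A) + log(priors)
  new_model("anderson", list(coef = A, const = const,
                             levels = levels(d$y), features = colnames(d$x)))
}

#' @export
predict.discrim_anderson <- function(object, newdata, ...) {
  m <- prep_newdata(object, newdata)
  scores <- sweep(m %*% object$coef, 2, object$const, "+")
  decode_scores(scores, object$levels)
}

# ---- Entropy classification tree ------------------------------------------

#' Classification tree, bagging, random forest and gradient boosting
#'
#' `fit_tree()` grows a single entropy-split classification tree until nodes
#' are pure (or smaller than 2), without pruning. `fit_bagging()` grows `B`
#' such trees on bootstrap resamples and classifies by plurality vote.
#' `fit_random_forest()` decorrelates the trees by sampling
#' \eqn{m = \lfloor\sqrt{p}\rfloor} candidate traits at each split.
#' `fit_boosting()` fits 500 sequential depth-2 trees by multinomial
#' gradient boosting with shrinkage 0.01.
#'
#' @inheritParams fit_fisher
#' @param B,n_trees Ensemble size (default 500).
#' @param bootstrap If `FALSE`, every bagged tree sees the full training set
#'   (with `B = 1` the ensemble degenerates to `fit_tree()`).
#' @param m Number of candidate traits per split (default
#'   \eqn{\lfloor\sqrt{p}\rfloor}).
#' @param depth Tree depth for boosting (default 2).
#' @param shrinkage Boosting learning rate in (0, 1] (default 0.01).
#' @param seed Integer seed for the resampling / subsampling streams.
#' @return A fitted `discrim_model`.
#' @export
fit_tree <- function(x, y) {
  d <- check_xy(x, y)
  df <- as.data.frame(d$x)
  names(df) <- make.names(colnames(d$x), unique = TRUE)
  df$.class <- d$y
  fit <- tree::tree(.class ~ ., data = df,
                    control = tree::tree.control(nobs = nrow(df),
                                                 mincut = 1, minsize = 2,
                                                 mindev = 0),
                    split = "deviance")
  new_model("tree", list(fit = fit, levels = levels(d$y),
                         features = colnames(d$x),
                         safe_names = setdiff(names(df), ".class")))
}

#' @export
predict.discrim_tree <- function(object, newdata, ...) {
  m <- prep_newdata(object, newdata)
  df <- as.data.frame(m)
  names(df) <- object$safe_names
  pr <- predict(object$fit, newdata = df, type = "vector")
  pr <- pr[, object$levels, drop = FALSE]
  decode_scores(pr, object$levels)
}

# ---- Bagging over entropy trees -------------------------------------------

#' @rdname fit_tree
#' @export
fit_bagging <- function(x, y, B = 500, bootstrap = TRUE, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  d <- check_xy(x, y)
  set.seed(child_seed(seed, 7L))
  n <- nrow(d$x)
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    # resamples missing a class entirely are redrawn (rare at n >= 20)
    while (bootstrap && length(unique(d$y[idx])) < 2) {
      idx <- sample.int(n, n, replace = TRUE)
    }
    trees[[b]] <- fit_tree(d$x[idx, , drop = FALSE], d$y[idx])
  }
  new_model("bagging", list(trees = trees, levels = levels(d$y),
                            features = colnames(d$x)))
}

bagged_votes <- function(trees, levels, newdata) {
  votes <- matrix(0, nrow(as_feature_matrix(newdata)), length(levels),
                  dimnames = list(NULL, levels))
  for (tr in trees) {
    pr <- predict(tr, newdata)
    tab <- one_hot(factor(pr, levels = levels))
    votes <- votes + tab
  }
  votes / length(trees)
}

#' @export
predict.discrim_bagging <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  votes <- bagged_votes(object$trees, object$levels, newdata)
  if (type == "prob") return(votes)
  decode_scores(votes, object$levels)
}

# ---- Random forest ---------------------------------------------------------

#' @rdname fit_tree
#' @export
fit_random_forest <- function(x, y, n_trees = 500, m = NULL, seed = 1) {
  if (n_trees < 1) stop("n_trees must be at least 1")
  d <- check_xy(x, y)
  if (is.null(m)) m <- max(1L, floor(sqrt(ncol(d$x))))
  set.seed(child_seed(seed, 11L))
  fit <- randomForest::randomForest(x = d$x, y = d$y, ntree = n_trees,
                                    mtry = m)
  new_model("random_forest", list(fit = fit, levels = levels(d$y),
                                  features = colnames(d$x)))
}

#' @export
predict.discrim_random_forest <- function(object, newdata, ...) {
  m <- prep_newdata(object, newdata)
  pr <- predict(object$fit, newdata = m, type = "response")
  factor(as.character(pr), levels = object$levels)
}

# ---- Multinomial gradient boosting ----------------------------------------

#' @rdname fit_tree
#' @export
fit_boosting <- function(x, y, n_trees = 500, depth = 2, shrinkage = 0.01,
                         seed = 1) {
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (depth < 1) stop("depth must be at least 1")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  d <- check_xy(x, y)
  K <- nlevels(d$y)
  fit <- xgb_train_compat(d$x, as.integer(d$y) - 1L, K, n_trees, depth,
                          shrinkage, seed)
  new_model("boosting", list(fit = fit, levels = levels(d$y),
                             features = colnames(d$x)))
}

# xgboost's R interface changed across major versions; keep to the stable
# xgb.DMatrix/xgb.train core, single-threaded for determinism.
xgb_train_compat <- function(x, ynum, K, n_trees, depth, shrinkage, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = ynum)
  params <- list(objective = "multi:softprob", num_class = K,
                 max_depth = depth, eta = shrinkage,
                 nthread = 1, seed = child_seed(seed, 13L))
  xgboost::xgb.train(params = params, data = dtrain, nrounds = n_trees,
                     verbose = 0)
}

#' @export
predict.discrim_boosting <- function(object, newdata, ...) {
  m <- prep_newdata(object, newdata)
  pr <- predict(object$fit, newdata = xgboost::xgb.DMatrix(data = m))
  if (!is.matrix(pr)) {       # older releases return a flat row-major vector
    pr <- matrix(pr, ncol = length(object$levels), byrow = TRUE)
  }
  decode_scores(pr, object$levels)
}
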