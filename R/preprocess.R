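#' Remove zero-variance traits
#'
#' Traits with zero sample variance carry no discriminatory information (in
#' the reference trial the sensory attributes clean cup, sweetness and
#' uniformity sit at the maximum score of 10 for every individual) and are
#' removed before classification. The order of the remaining traits is
#' preserved.
#'
#' @param data Phenotype data frame (trait columns + environment column).
#' @param env Name of the environment label column, kept as-is.
#' @return A list with `data` (filtered data frame) and `dropped`
#'   (character vector of removed trait names).
#' @examples
#' ds <- generate_phenotypes(n_per_env = 5, seed = 1)
#' drop_zero_variance(ds)$dropped
#' @export
drop_zero_variance <- function(data, env = "environment") {
  if (nrow(data) == 0) stop("dataset is empty")
  trait_cols <- setdiff(names(data), env)
  vars <- vapply(data[trait_cols], function(v) stats::var(as.numeric(v)),
                 numeric(1))
  vars[is.na(vars)] <- 0  # single observation: variance undefined, treat as 0
  dropped <- trait_cols[vars == 0]
  keep <- setdiff(trait_cols, dropped)
  if (length(keep) == 0) {
    stop("all traits have zero variance; nothing left to classify on")
  }
  out <- data[, c(keep, intersect(env, names(data))), drop = FALSE]
  list(data = out, dropped = dropped)
}

#' Min-max normalization with reusable scaling constants
#'
#' Rescales each trait linearly so that the training minimum maps to 0 and
#' the training maximum to 1. Test data are transformed with the *training*
#' constants and are deliberately not clipped, so test values outside the
#' training range extrapolate beyond \[0, 1\].
#'
#' @param train Training matrix or data frame (rows = observations).
#' @param apply_to Optional second matrix transformed with the training
#'   constants.
#' @return A list with `train`, `test` (or `NULL`), and `ranges` (a 2-row
#'   matrix of per-trait min and max).
#' @examples
#' mm <- minmax_normalize(cbind(a = c(2, 4, 6)))
#' mm$train[, "a"]  # 0, 0.5, 1
#' @export
minmax_normalize <- function(train, apply_to = NULL) {
  train <- as_feature_matrix(train)
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  flat <- which(hi == lo)
  if (length(flat) > 0) {
    stop("trait(s) with max = min in training data: ",
         paste(colnames(train)[flat], collapse = ", "),
         "; run drop_zero_variance() first")
  }
  scale_mat <- function(m) {
    sweep(sweep(m, 2, lo, "-"), 2, hi - lo, "/")
  }
  test <- if (is.null(apply_to)) NULL else scale_mat(as_feature_matrix(apply_to))
  ranges <- rbind(min = lo, max = hi)
  list(train = scale_mat(train), test = test, ranges = ranges)
}

#' @rdname minmax_normalize
#' @param x Normalized matrix to map back to original units.
#' @param ranges The `ranges` component returned by `minmax_normalize()`.
#' @export
minmax_denormalize <- function(x, ranges) {
  x <- as_feature_matrix(x)
  sweep(sweep(x, 2, ranges["max", ] - ranges["min", ], "*"),
        2, ranges["min", ], "+")
}

#' Repeated proportional stratified k-fold plan
#'
#' Builds the cross-validation scheme of the reference design: within each
#' repeat the individuals of every environment are shuffled and dealt
#' round-robin into `k` folds, so per-environment fold counts differ by at
#' most one (5 or 6 when 22 individuals meet 4 folds). The starting fold of
#' the round-robin rotates with both the repeat and the environment, so no
#' fold is systematically larger and — under the balanced reference design —
#' every fold holds exactly `n/k` observations in total.
#'
#' @param labels Factor (or coercible) of environment labels, one per
#'   observation.
#' @param k Number of folds (default 4).
#' @param n_repeats Number of independent randomizations (default 10).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `fold_plan` object: list with `assignment` (n x n_repeats
#'   integer matrix of fold indices), `k`, `n_repeats`, `labels`, `seed`.
#' @examples
#' fp <- make_fold_plan(rep(letters[1:4], each = 22), seed = 1)
#' table(fp$labels, fp$assignment[, 1])
#' @export
make_fold_plan <- function(labels, k = 4, n_repeats = 10, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  labels <- droplevels(as.factor(labels))
  if (k < 2) stop("k must be at least 2")
  counts <- table(labels)
  if (any(counts < k)) {
    stop("environment(s) with fewer than k observations: ",
         paste(names(counts)[counts < k], collapse = ", "))
  }
  n <- length(labels)
  assignment <- matrix(NA_integer_, n, n_repeats)
  set.seed(child_seed(seed, 101L))
  for (r in seq_len(n_repeats)) {
    for (e in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[e])
      perm <- sample(idx)
      start <- (r - 1 + e - 1) %% k
      assignment[perm, r] <- as.integer((seq_along(perm) - 1 + start) %% k + 1)
    }
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 n_repeats = as.integer(n_repeats), labels = labels,
                 seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan:", x$k, "folds x", x$n_repeats, "repeats,",
      length(x$labels), "observations\n")
  invisible(x)
}

#' Serialize / restore a fold plan as JSON
#'
#' @param plan A `fold_plan` object.
#' @param path File path.
#' @return `read_fold_plan()` returns the restored `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  obj <- list(assignment = unclass(plan$assignment),
              k = plan$k, n_repeats = plan$n_repeats,
              labels = as.character(plan$labels),
              label_levels = levels(plan$labels),
              seed = plan$seed)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(assignment = matrix(as.integer(obj$assignment),
                                     ncol = obj$n_repeats),
                 k = as.integer(obj$k), n_repeats = as.integer(obj$n_repeats),
                 labels = factor(obj$labels, levels = obj$label_levels),
                 seed = obj$seed),
            class = "fold_plan")
}
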