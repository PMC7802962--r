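# Dual trait-importance techniques for trained networks: disabling a trait
# by zeroing its first-layer weights, and decoupling it by permuting its
# test-input values. Both compare the modified network's apparent error rate
# with the intact network's on the same test set; neither mutates the
# fitted model.

#' Zero the first-layer weights of one input trait
#'
#' Returns a modified copy of a fitted network in which every first-layer
#' weight fed by input trait `trait` is set to zero (MLP: the trait's row of
#' the input weight matrix; RBF: the trait's coordinate of every hidden-unit
#' center). Only network models expose addressable input weights; other
#' methods raise an unsupported-technique error.
#'
#' @param model A fitted `discrim_mlp` or `discrim_rbf` model.
#' @param trait Trait name or column index.
#' @return A modified copy of the model; the original is untouched.
#' @export
zero_input_weights <- function(model, trait) {
  UseMethod("zero_input_weights")
}

resolve_trait <- function(model, trait) {
  if (is.character(trait)) {
    j <- match(trait, model$features)
    if (is.na(j)) stop("unknown trait '", trait, "'")
  } else {
    j <- as.integer(trait)
    if (j < 1 || j > length(model$features)) {
      stop("trait index ", j, " out of range")
    }
  }
  j
}

#' @export
zero_input_weights.discrim_mlp <- function(model, trait) {
  j <- resolve_trait(model, trait)
  model$W1[j, ] <- 0
  model
}

#' @export
zero_input_weights.discrim_rbf <- function(model, trait) {
  j <- resolve_trait(model, trait)
  model$centers[, j] <- 0
  model
}

#' @export
zero_input_weights.default <- function(model, trait) {
  stop("the zeroing technique is unsupported for method '",
       model$method, "': no addressable input weights")
}

model_aer <- function(model, x, truth) {
  pred <- predict(model, x)
  100 * mean(pred != factor(truth, levels = model$levels))
}

#' Trait-importance deltas on a test set
#'
#' `zeroing_delta()` computes \eqn{AER_{mod(j)} - AER_{com}}: the change in
#' apparent error rate on a test set after zeroing the first-layer weights
#' of trait `j`. `randomization_delta()` instead permutes the trait's values
#' across the test rows (a seeded uniform permutation, optionally averaged
#' over several draws), which decouples the trait from the response while
#' keeping its values inside the observed biological range; it applies to
#' any fitted model. Positive deltas mean the disturbed network classifies
#' worse, i.e. the trait matters.
#'
#' @param model A fitted `discrim_model` (a network for `zeroing_delta`).
#' @param x Test trait matrix/data frame (same columns as training).
#' @param truth True labels of the test rows.
#' @param trait Trait name or column index.
#' @param seed Integer seed for the permutation.
#' @param n_draws Number of permutation draws averaged (default 1).
#' @return The AER difference in percentage points.
#' @export
zeroing_delta <- function(model, x, truth, trait) {
  base <- model_aer(model, x, truth)
  mod <- zero_input_weights(model, trait)
  model_aer(mod, x, truth) - base
}

#' @rdname zeroing_delta
#' @export
randomization_delta <- function(model, x, truth, trait, seed = 1,
                                n_draws = 1) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2) stop("permutation needs at least 2 test rows")
  j <- resolve_trait(model, trait)
  base <- model_aer(model, x, truth)
  set.seed(child_seed(seed, 61L, j))
  deltas <- vapply(seq_len(n_draws), function(d) {
    xp <- x
    xp[, j] <- xp[sample.int(nrow(x)), j]
    model_aer(model, xp, truth) - base
  }, numeric(1))
  mean(deltas)
}

#' Relative importance of traits from AER deltas
#'
#' Sums each trait's AER deltas over all test sets, floors negative sums at
#' zero (a disturbance that *improves* the error carries no importance in
#' the percentage reading), and normalizes to percentages summing to 100:
#' \eqn{RI_j = 100 \cdot \sum_i \Delta_{ji} / \sum_j \sum_i \Delta_{ji}}.
#' The raw signed sums are kept alongside for transparency.
#'
#' @param deltas Numeric matrix of AER deltas, rows = traits, columns =
#'   test sets; rownames identify the traits.
#' @return Data frame with `trait`, `delta_sum` (raw signed sum) and `ri`
#'   (percent).
#' @export
relative_importance <- function(deltas) {
  deltas <- as.matrix(deltas)
  if (nrow(deltas) < 1 || ncol(deltas) < 1) {
    stop("need at least one trait and one test set")
  }
  sums <- rowSums(deltas)
  floored <- pmax(sums, 0)
  total <- sum(floored)
  if (total <= 0) {
    stop("no trait degrades the model; relative importance is undefined")
  }
  data.frame(trait = rownames(deltas) %||% paste0("trait", seq_along(sums)),
             delta_sum = unname(sums), ri = unname(100 * floored / total),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select important traits by mean relative importance
#'
#' Averages each trait's relative importance across the supplied
#' technique-by-network combinations (the four quadrants: zeroing and
#' randomization for each network) and keeps the traits whose mean exceeds
#' the cutoff.
#'
#' @param ri_list List of `relative_importance()` results (or named RI
#'   vectors) on a common trait list.
#' @param cutoff Mean-RI threshold in percent (default 15).
#' @return Character vector of selected trait names.
#' @examples
#' a <- data.frame(trait = c("t1", "t2"), delta_sum = c(3, 1), ri = c(75, 25))
#' b <- data.frame(trait = c("t1", "t2"), delta_sum = c(1, 3), ri = c(25, 75))
#' select_important(list(a, b), cutoff = 40)
#' @export
select_important <- function(ri_list, cutoff = 15) {
  vecs <- lapply(ri_list, function(r) {
    if (is.data.frame(r)) stats::setNames(r$ri, r$trait) else r
  })
  traits <- names(vecs[[1]])
  for (v in vecs) {
    if (!identical(names(v), traits)) {
      stop("relative-importance vectors have mismatched trait lists")
    }
  }
  mean_ri <- Reduce(`+`, vecs) / length(vecs)
  names(mean_ri)[mean_ri > cutoff]
}
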