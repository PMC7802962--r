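#' Control parameters for the classifier comparison
#'
#' Defaults mirror the reference study: 500-tree ensembles, depth-2
#' multinomial boosting with 1% shrinkage, two-hidden-layer MLPs with 5-40
#' units per layer trained for 5000 epochs, and RBF networks with 10-50
#' hidden units and radius 5-15 selected by inner validation.
#'
#' @param bagging_B,rf_trees,boost_trees Ensemble sizes.
#' @param boost_depth,boost_shrinkage Boosting tree depth and learning rate.
#' @param mlp_hidden List of `c(n1, n2)` MLP architecture candidates.
#' @param mlp_epochs,mlp_lambda,mlp_lr MLP training epochs, L2 penalty and
#'   initial learning rate.
#' @param rbf_neurons,rbf_radius RBF grid of hidden-unit counts and radii.
#' @param rbf_K,rbf_lambda RBF first-stage cluster count and output ridge.
#' @param rbf_inner_splits Inner splits averaged for the RBF grid selection.
#' @param inner_frac Inner-split fraction for architecture selection.
#' @return A named list of class `discrim_control`.
#' @export
discrim_control <- function(bagging_B = 500, rf_trees = 500,
                            boost_trees = 500, boost_depth = 2,
                            boost_shrinkage = 0.01,
                            mlp_hidden = list(c(20, 10)),
                            mlp_epochs = 5000,
                            mlp_lambda = c(0.003, 0.01, 0.03),
                            mlp_lr = 0.01,
                            rbf_neurons = seq(10, 50, by = 10),
                            rbf_radius = c(5, 10, 15),
                            rbf_K = 4, rbf_lambda = 1e-4,
                            rbf_inner_splits = 3,
                            inner_frac = 0.75) {
  structure(list(bagging_B = bagging_B, rf_trees = rf_trees,
                 boost_trees = boost_trees, boost_depth = boost_depth,
                 boost_shrinkage = boost_shrinkage, mlp_hidden = mlp_hidden,
                 mlp_epochs = mlp_epochs, mlp_lambda = mlp_lambda,
                 mlp_lr = mlp_lr, rbf_neurons = rbf_neurons,
                 rbf_radius = rbf_radius, rbf_K = rbf_K,
                 rbf_lambda = rbf_lambda,
                 rbf_inner_splits = rbf_inner_splits,
                 inner_frac = inner_frac),
            class = "discrim_control")
}

all_methods <- c("fisher", "anderson", "tree", "bagging", "random_forest",
                 "boosting", "mlp", "rbf")
network_methods <- c("mlp", "rbf")

fit_method <- function(method, x, y, control, seed) {
  switch(method,
         fisher = fit_fisher(x, y),
         anderson = fit_anderson(x, y),
         tree = fit_tree(x, y),
         bagging = fit_bagging(x, y, B = control$bagging_B, seed = seed),
         random_forest = fit_random_forest(x, y, n_trees = control$rf_trees,
                                           seed = seed),
         boosting = fit_boosting(x, y, n_trees = control$boost_trees,
                                 depth = control$boost_depth,
                                 shrinkage = control$boost_shrinkage,
                                 seed = seed),
         mlp = fit_mlp(x, y, hidden = control$mlp_hidden,
                       epochs = control$mlp_epochs,
                       lambda = control$mlp_lambda, lr0 = control$mlp_lr,
                       inner_frac = control$inner_frac, seed = seed),
         rbf = fit_rbf(x, y, neurons = control$rbf_neurons,
                       radius = control$rbf_radius, K = control$rbf_K,
                       lambda = control$rbf_lambda,
                       inner_frac = control$inner_frac,
                       inner_splits = control$rbf_inner_splits, seed = seed),
         stop("unknown method '", method, "'"))
}

#' Compare classifiers for multi-environment discrimination
#'
#' The package's central fitting function. Runs every requested classifier
#' through the same repeated proportional stratified k-fold cross-validation
#' plan, normalizing traits to \[0, 1\] with training-fold constants (or
#' once globally), and collects per-repeat apparent error rates,
#' fold-averaged confusion matrices, a Scott-Knott grouping of the method
#' means, and — for the two network methods — the dual zeroing /
#' randomization trait-importance analysis with relative-importance
#' normalization and cutoff selection.
#'
#' @param data Phenotype data frame: numeric trait columns plus an
#'   environment label column. Zero-variance traits are removed up front.
#' @param env Name of the environment column.
#' @param methods Character vector of classifiers to compare (default: all
#'   eight supervised methods).
#' @param k Folds per repeat (default 4).
#' @param n_repeats Cross-validation repeats (default 10).
#' @param alpha Scott-Knott significance level (default 0.05).
#' @param ri_cutoff Mean relative-importance cutoff in percent (default 15).
#' @param normalization `"fold"` rescales with training-fold min/max inside
#'   every fold (no leakage; the default) or `"global"` once on the full
#'   dataset.
#' @param importance Compute the trait-importance analysis for the fitted
#'   networks (default `TRUE` when any network method is requested).
#' @param control A [discrim_control()] list of per-method hyperparameters.
#' @param seed Master seed; all per-method, per-repeat, per-fold random
#'   streams are derived from it deterministically.
#' @return An `env_discrim` object with components `aer` (long data frame of
#'   per-repeat AERs), `summary` (per-method final AER = mean of repeats),
#'   `confusion` (fold-averaged matrix per method), `scott_knott`,
#'   `importance` (per network and technique, plus the selected traits),
#'   `fold_plan`, `dropped_traits` and the call.
#' @examples
#' ds <- generate_phenotypes(n_per_env = 8, seed = 1)
#' fit <- env_discrim(ds, methods = c("fisher", "tree"), n_repeats = 2,
#'                    seed = 1)
#' print(fit)
#' @export
env_discrim <- function(data, env = "environment", methods = all_methods,
                        k = 4, n_repeats = 10, alpha = 0.05, ri_cutoff = 15,
                        normalization = c("fold", "global"),
                        importance = any(methods %in% network_methods),
                        control = discrim_control(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  normalization <- match.arg(normalization)
  bad <- setdiff(methods, all_methods)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (ri_cutoff < 0 || ri_cutoff > 100) stop("ri_cutoff must be in [0, 100]")

  filt <- drop_zero_variance(data, env = env)
  xy <- phenotype_xy(filt$data, env = env)
  x <- as_feature_matrix(xy$x)
  y <- xy$y
  levels_y <- levels(y)
  traits <- colnames(x)

  plan <- make_fold_plan(y, k = k, n_repeats = n_repeats,
                         seed = child_seed(seed, 1L))
  if (normalization == "global") {
    x <- minmax_normalize(x)$train
  }

  imp_methods <- if (isTRUE(importance)) intersect(methods, network_methods)
                 else character(0)
  aer_rows <- list()
  conf <- stats::setNames(vector("list", length(methods)), methods)
  imp_deltas <- list()
  for (m in imp_methods) {
    imp_deltas[[m]] <- list(
      zeroing = matrix(NA_real_, length(traits), k * n_repeats,
                       dimnames = list(traits, NULL)),
      randomization = matrix(NA_real_, length(traits), k * n_repeats,
                             dimnames = list(traits, NULL)))
  }

  for (mi in seq_along(methods)) {
    method <- methods[mi]
    fold_mats <- vector("list", k * n_repeats)
    repeat_aer <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      fold_aer <- numeric(k)
      for (f in seq_len(k)) {
        test_idx <- which(plan$assignment[, r] == f)
        train_idx <- setdiff(seq_len(nrow(x)), test_idx)
        if (normalization == "fold") {
          mm <- minmax_normalize(x[train_idx, , drop = FALSE],
                                 x[test_idx, , drop = FALSE])
          x_tr <- mm$train; x_te <- mm$test
        } else {
          x_tr <- x[train_idx, , drop = FALSE]
          x_te <- x[test_idx, , drop = FALSE]
        }
        fit <- fit_method(method, x_tr, y[train_idx], control,
                          seed = child_seed(seed, 2L, mi, r, f))
        pred <- predict(fit, x_te)
        cmat <- confusion_matrix(y[test_idx], pred, levels_y)
        slot <- (r - 1) * k + f
        fold_mats[[slot]] <- cmat
        fold_aer[f] <- compute_aer(cmat)
        if (method %in% imp_methods) {
          for (j in seq_along(traits)) {
            imp_deltas[[method]]$zeroing[j, slot] <-
              zeroing_delta(fit, x_te, y[test_idx], traits[j])
            imp_deltas[[method]]$randomization[j, slot] <-
              randomization_delta(fit, x_te, y[test_idx], traits[j],
                                  seed = child_seed(seed, 3L, mi, r, f))
          }
        }
      }
      repeat_aer[r] <- mean(fold_aer)
    }
    conf[[method]] <- aggregate_confusion(fold_mats)
    aer_rows[[method]] <- data.frame(method = method,
                                     rep = seq_len(n_repeats),
                                     aer = repeat_aer,
                                     stringsAsFactors = FALSE)
  }

  aer <- do.call(rbind, aer_rows)
  rownames(aer) <- NULL
  summary_df <- stats::aggregate(aer ~ method, data = aer, FUN = mean)
  summary_df <- summary_df[match(methods, summary_df$method), ]
  rownames(summary_df) <- NULL

  sk <- if (length(methods) >= 2 && n_repeats >= 2) {
    scott_knott(split(aer$aer, aer$method)[methods], alpha = alpha)
  } else NULL

  imp <- NULL
  if (length(imp_methods) > 0) {
    imp <- list(deltas = imp_deltas, ri = list(), cutoff = ri_cutoff)
    for (m in imp_methods) {
      for (tech in c("zeroing", "randomization")) {
        imp$ri[[paste(m, tech, sep = ".")]] <-
          relative_importance(imp_deltas[[m]][[tech]])
      }
    }
    imp$selected <- tryCatch(select_important(imp$ri, cutoff = ri_cutoff),
                             error = function(e) character(0))
  }

  structure(list(aer = aer, summary = summary_df, confusion = conf,
                 scott_knott = sk, importance = imp, fold_plan = plan,
                 dropped_traits = filt$dropped, methods = methods,
                 traits = traits, alpha = alpha, normalization = normalization,
                 seed = seed, control = control, call = match.call()),
            class = "env_discrim")
}

#' @export
print.env_discrim <- function(x, ...) {
  cat("Multi-environment discrimination comparison\n")
  cat("  ", length(x$traits), "traits,",
      length(levels(x$fold_plan$labels)), "environments,",
      x$fold_plan$k, "folds x", x$fold_plan$n_repeats, "repeats\n")
  if (length(x$dropped_traits) > 0) {
    cat("  zero-variance traits removed:",
        paste(x$dropped_traits, collapse = ", "), "\n")
  }
  df <- x$summary
  if (!is.null(x$scott_knott)) {
    g <- x$scott_knott$groups
    df$group <- g$group[match(df$method, g$method)]
  }
  df$aer <- sprintf("%.2f", df$aer)
  names(df)[names(df) == "aer"] <- "AER(%)"
  print(df, row.names = FALSE)
  if (!is.null(x$importance) && length(x$importance$selected) > 0) {
    cat("Important traits (mean RI >", x$importance$cutoff, "%):",
        paste(x$importance$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.env_discrim <- function(object, ...) {
  print(object)
  cat("\nFold-averaged confusion matrices (rows = true environment):\n")
  for (m in names(object$confusion)) {
    cat("\n--", m, "(AER",
        sprintf("%.2f%%", compute_aer(object$confusion[[m]])), ")\n")
    print(round(object$confusion[[m]], 3))
  }
  invisible(object)
}

#' Plot a classifier comparison
#'
#' `which = "aer"` draws a boxplot of the per-repeat apparent error rates by
#' method, annotated with the Scott-Knott group letters; `which =
#' "importance"` draws the relative-importance profile of every
#' technique-by-network quadrant with the selection cutoff.
#'
#' @param x An `env_discrim` object.
#' @param which `"aer"` or `"importance"`.
#' @param ... Passed to the underlying graphics calls.
#' @return The object, invisibly.
#' @export
plot.env_discrim <- function(x, which = c("aer", "importance"), ...) {
  which <- match.arg(which)
  if (which == "aer") {
    vals <- split(x$aer$aer, x$aer$method)[x$methods]
    bx <- graphics::boxplot(vals, ylab = "Apparent error rate (%)",
                            las = 2, ...)
    if (!is.null(x$scott_knott)) {
      g <- x$scott_knott$groups
      lab <- g$group[match(x$methods, g$method)]
      graphics::text(seq_along(vals), bx$stats[5, ], labels = lab, pos = 3)
    }
  } else {
    if (is.null(x$importance)) {
      warning("no importance results in this fit")
      return(invisible(x))
    }
    ri <- x$importance$ri
    old <- graphics::par(mfrow = c(length(ri) %/% 2 + length(ri) %% 2,
                                   min(2, length(ri))),
                         mar = c(6, 4, 2, 1))
    on.exit(graphics::par(old))
    for (nm in names(ri)) {
      graphics::barplot(ri[[nm]]$ri, names.arg = ri[[nm]]$trait, las = 2,
                        main = nm, ylab = "RI (%)", cex.names = 0.6, ...)
      graphics::abline(h = x$importance$cutoff, lty = 2)
    }
  }
  invisible(x)
}

#' Export a comparison report as JSON
#'
#' Writes the per-repeat AERs, method summaries, Scott-Knott groups,
#' confusion matrices and (when present) the importance tables to a single
#' JSON file; rerunning the same configuration and seed reproduces the file
#' byte-identically.
#'
#' @param x An `env_discrim` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_discrim_report <- function(x, path) {
  stopifnot(inherits(x, "env_discrim"))
  obj <- list(
    seed = x$seed,
    methods = x$methods,
    dropped_traits = x$dropped_traits,
    aer = x$aer,
    summary = x$summary,
    scott_knott = if (!is.null(x$scott_knott)) x$scott_knott$groups,
    confusion = lapply(x$confusion, function(m) {
      list(labels = rownames(m), counts = unclass(as.matrix(m)))
    }),
    importance = if (!is.null(x$importance)) {
      list(ri = x$importance$ri, cutoff = x$importance$cutoff,
           selected = x$importance$selected)
    })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Published fold-averaged confusion matrices of the reference trial
#'
#' Returns the fold-averaged (10 repeats x 4 folds) confusion matrices
#' reported for the reference trial's classifiers on the real field data:
#' the two discriminant rules and the two networks. Row sums are 5.5
#' (the average per-environment test count) and the grand total 22.
#'
#' @param method One of `"Fisher"`, `"Anderson"`, `"RBF"`, `"MLP"`.
#' @return A 4x4 numeric matrix (rows = true environment).
#' @examples
#' compute_aer(reference_confusion("MLP"))  # 7.5
#' @export
reference_confusion <- function(method = c("MLP", "RBF", "Fisher",
                                           "Anderson")) {
  method <- match.arg(method)
  file <- if (method %in% c("MLP", "RBF")) "confusion_networks.csv" else
    "confusion_discriminant.csv"
  path <- system.file("extdata", file, package = "coffeeDiscrim",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  df <- df[df$method == method, ]
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$true_environment
  m
}

#' Export importance and confusion tables as CSV
#'
#' `write_importance_csv()` writes the tabular twin of the four-quadrant
#' importance figure: one row per trait, technique and network with the raw
#' signed delta sum, the relative importance in percent, and whether the
#' trait clears the mean-RI cutoff. `write_confusion_csv()` writes every
#' method's fold-averaged confusion matrix in the rows = true environment
#' layout, stacked long with a method column.
#'
#' @param x A fitted `env_discrim` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_importance_csv <- function(x, path) {
  stopifnot(inherits(x, "env_discrim"))
  if (is.null(x$importance)) stop("no importance results in this fit")
  rows <- list()
  for (nm in names(x$importance$ri)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ri <- x$importance$ri[[nm]]
    rows[[nm]] <- data.frame(trait = ri$trait, technique = parts[2],
                             network = parts[1], delta_sum = ri$delta_sum,
                             ri_percent = ri$ri,
                             selected = ri$trait %in% x$importance$selected,
                             stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance_csv
#' @export
write_confusion_csv <- function(x, path) {
  stopifnot(inherits(x, "env_discrim"))
  rows <- lapply(names(x$confusion), function(m) {
    cm <- as.matrix(x$confusion[[m]])
    df <- data.frame(method = m, true_environment = rownames(cm),
                     cm, check.names = FALSE, stringsAsFactors = FALSE)
    df$Total <- rowSums(cm)
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
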