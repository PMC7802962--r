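#' Apparent error rate of a confusion matrix
#'
#' The apparent error rate (AER) is the share of classifications falling off
#' the diagonal of the confusion matrix (rows = true environment, columns =
#' assigned environment), expressed in percent:
#' \eqn{AER = 100 \cdot \sum_{l \ne l'} m_{ll'} / N}. It applies equally to
#' single-fold integer matrices and to fold-averaged fractional matrices.
#'
#' @param cm Square numeric confusion matrix.
#' @return AER in percent.
#' @examples
#' compute_aer(diag(4) * 5)  # 0
#' @export
compute_aer <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0) stop("empty confusion matrix")
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has zero total count")
  100 * (total - sum(diag(cm))) / total
}

#' Fold-averaged confusion matrix
#'
#' Element-wise arithmetic mean of per-fold confusion matrices over all
#' folds and repeats; under the balanced reference design (22 per
#' environment, 4 folds) every row of the average totals 5.5 and the grand
#' total is 22.
#'
#' @param mats List of square confusion matrices with identical dimnames.
#' @return The averaged matrix.
#' @export
aggregate_confusion <- function(mats) {
  if (length(mats) == 0) stop("no confusion matrices supplied")
  ref <- dimnames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), dim(mats[[1]])) ||
        !identical(dimnames(m), ref)) {
      stop("confusion matrices have mismatched labels")
    }
  }
  out <- Reduce(`+`, lapply(mats, function(m) unclass(as.matrix(m)))) /
    length(mats)
  out
}

confusion_matrix <- function(truth, pred, levels) {
  table(true = factor(truth, levels = levels),
        assigned = factor(pred, levels = levels))
}

#' Scott-Knott grouping of method means
#'
#' Recursive means-clustering test: the methods are sorted by mean; among
#' all contiguous binary partitions of a candidate group the one maximizing
#' the between-group sum of squares \eqn{B_0} is tested with
#' \eqn{\lambda = \pi / (2(\pi - 2)) \cdot B_0 / \hat\sigma_0^2}
#' against a chi-squared distribution with \eqn{k / (\pi - 2)} degrees of
#' freedom, where \eqn{\hat\sigma_0^2} blends the maximum-likelihood
#' variance of the means in the group under test with the replicate-level
#' error variance (the classical formulation). A significant split recurses
#' into both halves; otherwise the group is final. Groups are therefore
#' always contiguous intervals of the mean-sorted method list and are
#' labelled with letters in mean order (letter "a" = smallest mean).
#'
#' If every replicate vector is identical across methods a single group is
#' returned; if the variance estimate is exactly zero while means differ,
#' the split is accepted unconditionally (the means are then separated with
#' certainty).
#'
#' @param values Named list of replicate vectors (one per method), or a
#'   matrix with one row per method, e.g. the 10 repeat-level AERs.
#' @param alpha Significance level of the chi-squared test (default 0.05).
#' @return A `scott_knott` object: data frame `groups` (method, mean,
#'   group letter, ordered by mean) plus a list of the tested splits with
#'   their \eqn{B_0}, \eqn{\hat\sigma_0^2}, \eqn{\lambda}, degrees of
#'   freedom and critical value.
#' @examples
#' x <- list(a = c(7.4, 7.6), b = c(7.8, 8.0), c = c(24.0, 24.2))
#' scott_knott(x)$groups
#' @export
scott_knott <- function(values, alpha = 0.05) {
  if (is.matrix(values)) {
    values <- stats::setNames(lapply(seq_len(nrow(values)),
                                     function(i) values[i, ]),
                              rownames(values))
  }
  k_all <- length(values)
  if (k_all == 0) stop("no methods supplied")
  means <- vapply(values, mean, numeric(1))
  if (is.null(names(means))) names(means) <- paste0("m", seq_along(means))
  reps <- vapply(values, length, integer(1))
  if (k_all >= 2 && any(reps < 2)) {
    stop("need at least 2 replicates per method")
  }

  # replicate-level error variance (pooled within-method), as in a one-way
  # ANOVA; nu error df; s2y variance of a method mean
  nu <- sum(reps - 1)
  sse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  s2y <- if (nu > 0) (sse / nu) / mean(reps) else 0

  ord <- order(means)
  sorted <- means[ord]
  splits <- list()
  groups <- rep(NA_integer_, k_all)
  counter <- 0L

  recurse <- function(idx) {
    g <- length(idx)
    if (g < 2) {
      counter <<- counter + 1L
      groups[idx] <<- counter
      return(invisible())
    }
    m <- sorted[idx]
    b0 <- vapply(seq_len(g - 1), function(j) {
      t1 <- sum(m[1:j]); t2 <- sum(m[(j + 1):g])
      t1^2 / j + t2^2 / (g - j) - (t1 + t2)^2 / g
    }, numeric(1))
    jbest <- which.max(b0)
    B0 <- b0[jbest]
    sigma0 <- (sum((m - mean(m))^2) + nu * s2y) / (g + nu)
    df <- g / (pi - 2)
    crit <- stats::qchisq(1 - alpha, df)
    lambda <- if (sigma0 > 0) pi / (2 * (pi - 2)) * B0 / sigma0 else {
      if (B0 > 0) Inf else 0     # all means equal: nothing to split
    }
    splits[[length(splits) + 1L]] <<- list(
      members = names(m), B0 = B0, sigma0_sq = sigma0, lambda = lambda,
      df = df, critical = crit, significant = lambda > crit)
    if (lambda > crit) {
      recurse(idx[1:jbest])
      recurse(idx[(jbest + 1):g])
    } else {
      counter <<- counter + 1L
      groups[idx] <<- counter
    }
    invisible()
  }
  recurse(seq_len(k_all))

  out <- data.frame(method = names(sorted), mean = unname(sorted),
                    group = letters[groups], stringsAsFactors = FALSE)
  structure(list(groups = out, splits = splits, alpha = alpha,
                 error_df = nu, mean_variance = s2y),
            class = "scott_knott")
}

#' @export
print.scott_knott <- function(x, ...) {
  cat("Scott-Knott grouping (alpha =", x$alpha, "):\n")
  df <- x$groups
  df$mean <- sprintf("%.3f", df$mean)
  print(df, row.names = FALSE)
  invisible(x)
}
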