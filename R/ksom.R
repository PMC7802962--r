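#' Kohonen self-organizing map clustering
#'
#' Unsupervised competitive-learning map with a small (default 4-unit, 2x2)
#' grid, trained by the classic online rule for a fixed number of
#' iterations. Similarity is the standardized average Euclidean distance:
#' traits are range-standardized to \[0, 1\] and the squared Euclidean
#' distance is divided by the trait count, so every trait contributes on a
#' common scale. No label information is used; when labels are supplied a
#' cross-tabulation of winning unit against label is attached so the match
#' between emergent clusters and environments can be inspected.
#'
#' @param x Matrix or data frame of traits.
#' @param neurons Number of map units (default 4, laid out on a near-square
#'   grid).
#' @param iterations Online training iterations (default 1000).
#' @param seed Integer seed.
#' @param labels Optional true labels for the cross-tabulation.
#' @return A `ksom` object: list with `units` (codebook vectors in
#'   standardized space), `assignment` (winning unit per observation),
#'   `crosstab` (or `NULL`), and the scaling constants.
#' @export
fit_ksom <- function(x, neurons = 4, iterations = 1000, seed = 1,
                     labels = NULL) {
  if (iterations < 1) stop("iterations must be at least 1")
  x <- as_feature_matrix(x)
  if (nrow(x) < neurons) stop("need at least as many observations as neurons")
  lo <- apply(x, 2, min)
  rg <- apply(x, 2, max) - lo
  rg[rg == 0] <- 1                      # constant traits contribute 0
  z <- sweep(sweep(x, 2, lo, "-"), 2, rg, "/")
  p <- ncol(z)

  # map topology: near-square grid, unit positions for the neighborhood
  gw <- ceiling(sqrt(neurons))
  pos <- cbind((seq_len(neurons) - 1) %% gw, (seq_len(neurons) - 1) %/% gw)
  grid_d <- as.matrix(stats::dist(pos))

  set.seed(child_seed(seed, 51L))
  units <- z[sample.int(nrow(z), neurons), , drop = FALSE]
  lr_seq <- 0.5 * (0.02 / 0.5)^(seq_len(iterations) / iterations)
  sg_seq <- pmax(1.0 * (1 - seq_len(iterations) / iterations), 0.1)
  order_idx <- sample.int(nrow(z), iterations, replace = TRUE)
  for (t in seq_len(iterations)) {
    v <- z[order_idx[t], ]
    d <- rowSums(sweep(units, 2, v, "-")^2) / p
    bmu <- which.min(d)
    h <- exp(-grid_d[bmu, ]^2 / (2 * sg_seq[t]^2))
    units <- units + lr_seq[t] * h * sweep(-units, 2, v, "+")
  }

  d_all <- outer(rowSums(z^2), rowSums(units^2), "+") - 2 * z %*% t(units)
  assignment <- apply(d_all / p, 1, which.min)
  crosstab <- if (!is.null(labels)) {
    table(unit = factor(assignment, levels = seq_len(neurons)),
          label = as.factor(labels))
  } else NULL
  structure(list(units = units, assignment = assignment, crosstab = crosstab,
                 neurons = neurons, iterations = iterations,
                 scale = list(min = lo, range = rg), seed = seed),
            class = "ksom")
}

#' @export
print.ksom <- function(x, ...) {
  cat("Kohonen map:", x$neurons, "units,", x$iterations, "iterations\n")
  cat("Unit occupancy:",
      paste(tabulate(x$assignment, x$neurons), collapse = ", "), "\n")
  if (!is.null(x$crosstab)) {
    cat("Cross-tabulation against labels:\n")
    print(x$crosstab)
  }
  invisible(x)
}
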