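# Synthetic phenotype generation from the per-environment trait moments.
#
# Traits are modelled as independent truncated normals per environment (only
# means and SDs are published; no covariance structure is available). Ordinal
# scores are round-then-clip of a truncated normal. Pre-harvest values of the
# two Araponga environments are drawn once per individual and shared, because
# those environments are the same plants split by post-harvest processing.

# Truncated-normal draws by inverse-CDF; exact and vectorized.
rtruncnorm_q <- function(n, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# Mean/variance of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (al * da - be * db) / z - ((da - db) / z)^2)
  c(mean = unname(m), var = unname(v))
}

# Solve for latent (mu, sigma) such that the truncated normal on [a, b]
# has the target mean/sd. When the bounds are far (> 6 sd) the identity
# is returned: truncation is then numerically irrelevant.
match_truncnorm_params <- function(m, s, a, b) {
  if ((m - a) > 6 * s && (b - m) > 6 * s) {
    return(c(mu = m, sigma = s))
  }
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), a, b)
    if (!all(is.finite(mom)) || mom["var"] < 0) return(1e10)
    (mom["mean"] - m)^2 / s^2 + (sqrt(mom["var"]) - s)^2 / s^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Expected value of round-then-clip applied to a truncated normal; used to
# quantify the discretization bias of ordinal scores in closed form.
ordinal_expected_mean <- function(mu, sigma, a, b) {
  vals <- seq(a, b)
  cuts <- c(-Inf, vals[-length(vals)] + 0.5, Inf)
  z <- stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma)
  pr <- (pmin(stats::pnorm(cuts[-1], mu, sigma), stats::pnorm(b, mu, sigma)) -
           pmax(stats::pnorm(cuts[-length(cuts)], mu, sigma),
                stats::pnorm(a, mu, sigma))) / z
  pr <- pmax(pr, 0)
  sum(vals * pr)
}

draw_trait <- function(n, kind, mean, sd, lower, upper) {
  if (kind == "constant") return(rep(mean, n))
  if (kind %in% c("continuous", "percentage")) {
    par <- match_truncnorm_params(mean, sd, lower, upper)
    return(rtruncnorm_q(n, par["mu"], par["sigma"], lower, upper))
  }
  if (kind %in% c("ordinal_score", "count")) {
    x <- rtruncnorm_q(n, mean, sd, lower, upper)
    return(pmin(pmax(round(x), lower), upper))
  }
  stop("unknown trait kind '", kind, "'")
}

#' Generate a synthetic multi-environment phenotype dataset
#'
#' Draws `n_per_env` individuals for each environment from independent
#' truncated normal distributions with the per-environment (mean, sd) of each
#' trait. Continuous and percentage traits use latent parameters solved so
#' that the truncated distribution reproduces the target moments; ordinal
#' scores are rounded to the nearest integer inside their valid range (so
#' their realized means carry a small, quantifiable discretization bias);
#' constant traits are set to their declared value. Pre-harvest trait values
#' of the two environments sharing the Araponga site are drawn once per
#' individual and copied between the matched rows, reproducing the redundancy
#' of the same plants being split by post-harvest processing.
#'
#' @param specs A [coffee_trait_specs()] object (or compatible).
#' @param n_per_env Individuals per environment. Default 22, the per-fold
#'   arithmetic of the original design (4 folds of ~22 over 88 individuals).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A `phenotype_data` data frame: one numeric column per trait plus a
#'   factor column `environment`, with the trait specification attached as
#'   attribute `trait_specs` and the seed as attribute `seed`.
#' @examples
#' ds <- generate_phenotypes(n_per_env = 10, seed = 1)
#' table(ds$environment)
#' @export
generate_phenotypes <- function(specs = coffee_trait_specs(), n_per_env = NULL,
                                seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible generation")
  }
  validate_trait_specs(specs)
  traits <- specs$traits
  envs <- specs$environments
  if (is.null(n_per_env)) n_per_env <- envs$n_individuals else {
    envs$n_individuals <- n_per_env
  }
  if (any(envs$n_individuals < 2)) {
    stop("each environment needs at least 2 individuals")
  }

  arap <- envs$name[envs$site == "Araponga"]
  arap_ref <- arap[1]   # values drawn here are shared with the second entry
  arap_dup <- arap[2]
  if (envs$n_individuals[envs$name == arap_ref] !=
      envs$n_individuals[envs$name == arap_dup]) {
    stop("the two Araponga environments must have equal n to pair individuals")
  }

  set.seed(seed)
  env_blocks <- list()
  for (e in envs$name) {
    n <- envs$n_individuals[envs$name == e]
    block <- matrix(NA_real_, n, nrow(traits),
                    dimnames = list(NULL, traits$trait))
    for (i in seq_len(nrow(traits))) {
      tr <- traits$trait[i]
      if (e == arap_dup && traits$phase[i] == "pre_harvest") next # copied below
      p <- specs$params[specs$params$trait == tr &
                          specs$params$environment == e, ]
      block[, i] <- draw_trait(n, traits$kind[i], p$mean, p$sd,
                               traits$lower[i], traits$upper[i])
    }
    env_blocks[[e]] <- block
  }
  pre <- traits$trait[traits$phase == "pre_harvest"]
  env_blocks[[arap_dup]][, pre] <- env_blocks[[arap_ref]][, pre]

  values <- do.call(rbind, env_blocks)
  out <- as.data.frame(values)
  out$environment <- factor(rep(envs$name, envs$n_individuals),
                            levels = envs$name)
  rownames(out) <- NULL
  structure(out, trait_specs = specs, seed = seed,
            class = c("phenotype_data", "data.frame"))
}

#' Split a phenotype data frame into traits and labels
#'
#' @param data A data frame with trait columns and an environment column.
#' @param env Name of the environment label column.
#' @return A list with `x` (numeric trait data frame) and `y` (factor labels).
#' @export
phenotype_xy <- function(data, env = "environment") {
  if (!env %in% names(data)) {
    stop("data has no '", env, "' column")
  }
  y <- droplevels(as.factor(data[[env]]))
  x <- data[, setdiff(names(data), env), drop = FALSE]
  nonnum <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    stop("non-numeric trait column(s): ", paste(nonnum, collapse = ", "))
  }
  if (anyNA(x)) stop("missing values in trait columns")
  list(x = x, y = y)
}

#' Write / read a phenotype dataset as CSV
#'
#' `write_phenotypes()` writes trait columns at full double precision
#' (`%.17g`) so that `read_phenotypes()` reproduces the values bit-exactly.
#'
#' @param data Phenotype data frame (trait columns + `environment`).
#' @param path File path.
#' @param env Name of the environment label column.
#' @return `read_phenotypes()` returns a `phenotype_data` data frame.
#' @export
write_phenotypes <- function(data, path, env = "environment") {
  if (!env %in% names(data)) stop("data has no '", env, "' column")
  out <- data
  for (nm in setdiff(names(out), env)) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path, env = "environment") {
  first <- readLines(path, n = 2L)
  if (length(first) == 0 || nchar(trimws(first[1])) == 0) {
    stop("no observations: file '", path, "' is empty")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("no observations in '", path, "'")
  if (!env %in% names(df)) {
    stop("CSV is missing the '", env, "' column")
  }
  if (anyDuplicated(names(df))) {
    stop("duplicate trait names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  for (nm in setdiff(names(df), env)) {
    if (!is.numeric(df[[nm]])) {
      stop("non-numeric value in trait column '", nm, "'")
    }
    df[[nm]] <- as.double(df[[nm]])
  }
  df[[env]] <- factor(df[[env]], levels = unique(df[[env]]))
  structure(df, class = c("phenotype_data", "data.frame"))
}
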