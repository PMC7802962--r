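#' Reference trait and environment parameterization of the coffee trial
#'
#' Loads the packaged parameterization of the Matas de Minas multi-environment
#' coffee trial: 31 morpho-agronomic, post-harvest and sensory traits with
#' per-environment means and standard deviations, and the four environments
#' (three production sites, with the Araponga site split into pulped and
#' natural post-harvest processing). Three sensory attributes (clean cup,
#' sweetness, uniformity) are constant at their maximum score of 10 in every
#' environment.
#'
#' Each trait carries a `kind` (`continuous`, `ordinal_score`, `percentage`,
#' or `constant`), a measurement `phase` (`pre_harvest`, `post_harvest`,
#' `sensory`), a closed valid range, and a (mean, sd) pair per environment.
#' Pre-harvest traits are measured on the plant before processing, so the two
#' Araponga environments share identical pre-harvest parameters (and, in
#' generated data, identical pre-harvest values for matched individuals).
#'
#' @param path Optional path to an alternative trait parameter CSV laid out
#'   like the packaged one (columns `trait`, `kind`, `phase`, `lower`,
#'   `upper`, and `env_<name>_mean` / `env_<name>_sd` pairs).
#' @param env_path Optional path to an alternative environment CSV
#'   (columns `name`, `site`, `process`, `altitude_m`, `n_individuals`).
#'
#' @return An object of class `trait_specs`: a list with components
#'   \describe{
#'     \item{traits}{data frame of trait metadata (one row per trait).}
#'     \item{params}{long data frame `trait`, `environment`, `mean`, `sd`.}
#'     \item{environments}{data frame of environment descriptors.}
#'   }
#' @examples
#' specs <- coffee_trait_specs()
#' nrow(specs$traits)  # 31
#' subset(specs$params, trait == "PH")
#' @export
coffee_trait_specs <- function(path = NULL, env_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trait_parameters.csv",
                        package = "coffeeDiscrim", mustWork = TRUE)
  }
  if (is.null(env_path)) {
    env_path <- system.file("extdata", "environments.csv",
                            package = "coffeeDiscrim", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  envs <- utils::read.csv(env_path, stringsAsFactors = FALSE)

  needed <- c("trait", "kind", "phase", "lower", "upper")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    stop("trait parameter file is missing column(s): ", paste(miss, collapse = ", "))
  }
  env_names <- envs$name
  for (e in env_names) {
    for (stat in c("mean", "sd")) {
      col <- paste0("env_", e, "_", stat)
      if (!col %in% names(raw)) {
        stop("trait parameter file is missing column '", col, "'")
      }
      bad <- which(is.na(raw[[col]]))
      if (length(bad) > 0) {
        stop("missing ", stat, " for trait '", raw$trait[bad[1]],
             "' in environment '", e, "'")
      }
    }
  }
  if (anyDuplicated(raw$trait)) {
    stop("duplicate trait names in parameter file: ",
         paste(unique(raw$trait[duplicated(raw$trait)]), collapse = ", "))
  }

  traits <- raw[, needed]
  params <- do.call(rbind, lapply(env_names, function(e) {
    data.frame(trait = raw$trait, environment = e,
               mean = raw[[paste0("env_", e, "_mean")]],
               sd = raw[[paste0("env_", e, "_sd")]],
               stringsAsFactors = FALSE)
  }))
  specs <- structure(list(traits = traits, params = params, environments = envs),
                     class = "trait_specs")
  validate_trait_specs(specs)
  specs
}

validate_trait_specs <- function(specs) {
  traits <- specs$traits
  params <- specs$params
  envs <- specs$environments

  kinds <- c("continuous", "ordinal_score", "percentage", "count", "constant")
  bad <- setdiff(traits$kind, kinds)
  if (length(bad) > 0) stop("unknown trait kind(s): ", paste(bad, collapse = ", "))
  phases <- c("pre_harvest", "post_harvest", "sensory")
  bad <- setdiff(traits$phase, phases)
  if (length(bad) > 0) stop("unknown trait phase(s): ", paste(bad, collapse = ", "))

  for (i in seq_len(nrow(traits))) {
    tr <- traits$trait[i]
    p <- params[params$trait == tr, ]
    if (nrow(p) != nrow(envs)) {
      stop("trait '", tr, "' lacks parameters for every environment")
    }
    if (any(p$mean < traits$lower[i] | p$mean > traits$upper[i])) {
      stop("trait '", tr, "' has a mean outside its valid range [",
           traits$lower[i], ", ", traits$upper[i], "]")
    }
    if (any(p$sd < 0)) stop("trait '", tr, "' has a negative sd")
    if (traits$kind[i] == "constant" && any(p$sd != 0)) {
      stop("constant trait '", tr, "' must have sd = 0")
    }
    if (traits$kind[i] != "constant" && any(p$sd == 0)) {
      stop("non-constant trait '", tr, "' has sd = 0")
    }
  }

  arap <- envs[envs$site == "Araponga", ]
  if (nrow(arap) != 2 || length(unique(arap$process)) != 2) {
    stop("exactly two environments must share the Araponga site and differ in process")
  }
  invisible(specs)
}

#' @export
print.trait_specs <- function(x, ...) {
  cat("Trait specification:", nrow(x$traits), "traits,",
      nrow(x$environments), "environments\n")
  cat("  kinds:", paste(names(table(x$traits$kind)),
                        table(x$traits$kind), collapse = ", "), "\n")
  cat("  environments:", paste(x$environments$name, collapse = ", "), "\n")
  invisible(x)
}
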