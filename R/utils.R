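# internal helpers shared across modules

# Deterministic child-seed derivation: mixing in a Lehmer-style modular
# multiply keeps every stream reproducible from one master seed while
# decoupling streams (adding a method must not perturb another method's
# random numbers). All arithmetic stays below 2^53 so doubles are exact.
child_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed %% m)
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 1) %% m
  }
  as.integer(s)
}

one_hot <- function(f) {
  f <- as.factor(f)
  y <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

# argmax decoding with deterministic tie-break on the lowest class index
decode_scores <- function(scores, levels) {
  idx <- apply(scores, 1L, which.max)
  factor(levels[idx], levels = levels)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    ok <- vapply(x, is.numeric, logical(1))
    if (!all(ok)) {
      stop("non-numeric trait column(s): ", paste(names(x)[!ok], collapse = ", "))
    }
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

# stratified index split used for inner architecture selection
stratified_split <- function(y, frac, seed) {
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- max(1L, floor(length(idx) * frac))
    train <- c(train, sample(idx)[seq_len(n_tr)])
  }
  sort(train)
}
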