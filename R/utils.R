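# internal helpers

# Run `expr` under an explicit seed without disturbing the caller's RNG
# state; with seed=NULL the ambient RNG stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a per-stage child seed from a master seed (kept < 2^31).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + 97 * k) %% .Machine$integer.max)
}

# Stratified k-fold assignment: within each class, shuffle and deal round
# robin so every fold sees every class where counts allow.
stratifiedFolds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

stopifnot_scalar_pos <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
}
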