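# Seeded sections that do not disturb the caller's RNG state.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

# Derived stream seeds stay below 2^31 - 1.
.derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + p * 7919 + 1) %% 2147483629
  as.integer(s)
}
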