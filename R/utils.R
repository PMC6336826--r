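# internal helpers: argument checking and deterministic per-trial seeding

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Stable 32-bit string hash (polynomial rolling hash, prime modulus).
# Used to derive independent per-trial RNG streams from one user seed so
# trials are reproducible individually and in any order.
hash32 <- function(s) {
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(as.character(s))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

trial_seed <- function(seed, trial_id) {
  as.integer((as.numeric(seed) %% 2147483647 + hash32(trial_id)) %% 2147483647)
}

# evaluate expr with a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
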