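# internal helpers: argument checking and seeded evaluation

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0)
    stopf("`%s` must be strictly positive", name)
  invisible(x)
}

# All stochastic operations funnel through this wrapper so that a fixed seed
# gives byte-identical results without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  seed <- as.integer(seed)
  withr::with_seed(seed, code)
}

# Deterministic sub-seed derivation: keeps derived seeds positive and well
# below 2^31 even for large master seeds.
derive_seed <- function(master, index) {
  (as.integer(master) %% 1000000L) * 1000L + as.integer(index) %% 1000L
}

# stable hash of an R object (used to assert shared bases across conditions)
object_hash <- function(x) rlang::hash(x)
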