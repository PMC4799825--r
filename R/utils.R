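# Internal helpers: seed handling and argument checks.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL leaves
# the RNG stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Counter-based derivation of per-stage seeds from a master seed.
# Exact in double arithmetic (operands < 2^53) and always < 2^31,
# so adding a pipeline stage never perturbs earlier stages' draws.
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.double(master)) * 48271 + as.double(offset) * 16807) %%
               2147483629)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
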