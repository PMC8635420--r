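# internal helpers shared across modules

# Evaluate `code` in the caller's frame under a temporary RNG state seeded
# with `seed`; the global RNG state is restored afterwards, so library code
# never perturbs the user's random stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

# Derive a stream-specific child seed from a run seed; stays inside the
# 32-bit signed integer range R requires of set.seed().
seed_from <- function(seed, stream) {
  as.integer((abs(as.double(seed)) %% 65521 * 31627 +
                abs(as.double(stream)) %% 65521 * 7919) %% 2147483629)
}

# %||% without importing rlang's at call sites that predate the import
`%||%` <- function(x, y) if (is.null(x)) y else x

logistic <- function(x) 1 / (1 + exp(-x))
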