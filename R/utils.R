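# Small internal helpers.

.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards. seed = NULL means
# "use the current RNG stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ppiface <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x) && x > 0
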