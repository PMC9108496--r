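# internal helpers shared across modules

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# derive a child seed from a base seed and a stream index; stays < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 7919) %%
    2147483647)
}

# run code under a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_emofc <- function(msg, class = "emofc_error") {
  rlang::abort(msg, class = class)
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
    x != as.integer(x)) {
    abort_emofc(sprintf("`%s` must be a single integer >= %s", name, min),
      class = "emofc_config_error"
    )
  }
}
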