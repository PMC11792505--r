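# Internal helpers: seed management and deterministic derived streams.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
# RNG kind is pinned so results do not depend on session defaults.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range. Used so that
# independent Monte-Carlo streams (e.g. one per site pair) do not depend on
# evaluation order: removal runs then replay the identical stream.
derive_seed <- function(seed, index) {
  as.integer((abs(as.double(seed)) %% 86243) * 24593 + (as.double(index) %% 24593)) %% 2147483647L
}

# Tip-label permutations over a pool of n taxa; depends only on (seed, n).
make_tip_perms <- function(seed, n_taxa, n_reps) {
  with_seed(seed, {
    p <- matrix(0L, nrow = n_reps, ncol = n_taxa)
    for (r in seq_len(n_reps)) p[r, ] <- sample.int(n_taxa)
    p
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
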