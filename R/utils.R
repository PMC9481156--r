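## Small internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Encode (frame, cell_id) pairs as a single numeric key. Frames and ids are
# assumed < 1e7, which the package's data sources respect.
node_code <- function(frame, cell_id) {
  frame * 1e7 + cell_id
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of distinct sub-seeds from one user-facing seed, staying
# inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 99991L * seq_len(n)) %% .Machine$integer.max
}
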