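# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# split a string into a raw byte vector (fast per-character ops)
seq_bytes <- function(s) charToRaw(s)
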