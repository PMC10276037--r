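# Internal helpers: seeded evaluation and derived sub-streams.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-bit sub-seed derived from (root seed, named stream, index),
# so each pipeline stage draws from its own reproducible stream.
sub_seed <- function(seed, stream, k = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.numeric(seed) %% 2147483647) * 48271 + h * 7919 + as.numeric(k) * 30269
  as.integer(s %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("porediff_invalid_input", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_generation <- function(...) {
  stop(structure(class = c("porediff_generation_failure", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
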