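# Evaluate a thunk under a temporary RNG state; the caller's stream is
# untouched. seed = NULL runs on the current stream.
.with_seed <- function(seed, thunk) {
  if (is.null(seed)) return(thunk())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  thunk()
}

# derive a bounded child seed from a parent seed and a stream index
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}
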