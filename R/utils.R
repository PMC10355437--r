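# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a reproducible per-task seed from a master seed, kept inside .Machine
# integer range so it is portable
derive_seed <- function(master, id) {
  as.integer((as.double(master) * 7919 + as.double(id) * 104729) %% 2147483629)
}

upper_tri_vec <- function(M) M[upper.tri(M)]
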