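# Internal helpers.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards; seed = NULL evaluates as-is under the current stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# log(mean(exp(x))) without overflow
logMeanExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# All ordered off-diagonal index pairs of an n-node network, as a 2-column
# matrix (source, target), column-major over targets.
orderedPairs <- function(n) {
  idx <- which(row(diag(n)) != col(diag(n)))
  cbind(source = ((idx - 1) %% n) + 1, target = ((idx - 1) %/% n) + 1)
}
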