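# Internal helpers shared across modules.

# Run expr under a given seed, restoring the caller's RNG state afterwards.
# seed = NA uses (and advances) the ambient RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce a DFM object or plain matrix to its numeric matrix, validating
# through the DFM constructor when a plain matrix is given.
asDFMMatrix <- function(x) {
  if (is(x, "DFM")) return(x@mat)
  m <- DFM(x)  # validates symmetry / diagonal / sign
  m@mat
}

dfmLabelsOf <- function(x) {
  if (is(x, "DFM")) x@labels else paste0("R", seq_len(nrow(as.matrix(x))))
}

# Derive a 31-bit sub-seed from a master seed and a string tag, so batch
# runs are reproducible and restartable pair by pair.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}
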