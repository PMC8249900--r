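# run code under a temporary RNG state; the caller's stream is untouched
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

# derive a bounded child seed from a master seed and a counter
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629 + 1)
}

# coerce a "connectome set" (E x N matrix, list of FunctionalConnectome, or a
# single numeric edge vector) to an E x N edge matrix
.edgeMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, ncol = 1L))
  if (is.list(x)) {
    vs <- lapply(x, function(fc) {
      if (is(fc, "FunctionalConnectome")) vectorizeConnectome(fc)
      else as.numeric(fc)
    })
    E <- unique(lengths(vs))
    if (length(E) != 1L) stop("connectomes have inconsistent edge counts")
    m <- do.call(cbind, vs)
    nm <- vapply(x, function(fc)
      if (is(fc, "FunctionalConnectome")) fc@subjectID else NA_character_,
      character(1))
    if (!anyNA(nm)) colnames(m) <- nm
    return(m)
  }
  stop("cannot interpret object of class ", class(x)[1], " as connectome set")
}
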