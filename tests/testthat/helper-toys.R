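# shared fixtures built in code

# symmetric correlation-style matrix from an edge vector
toyMatrix <- function(vec, R) devectorizeEdges(vec, R)

# small paired edge-matrix cohort with a planted linear outcome:
# edge matrices E x N, outcome = 2*sPos - 1*sNeg + 3 (noise-free)
toyLinearCohort <- function(N = 6, E = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(E * N, -0.5, 0.5), E, N,
              dimnames = list(NULL, sprintf("s%02d", seq_len(N))))
  mask <- edgeMask(positive = seq_len(E) %in% 1:3,
                   negative = seq_len(E) %in% 4:5,
                   threshold = 0.1, outcome = "toy")
  s <- maskStrengths(X, mask)
  list(X = X, mask = mask, y = 3 + 2 * s$pos - 1 * s$neg)
}

# paired restA/restB matrices with subject-stable signal + session noise
toyPairedCohort <- function(N = 8, E = 60, noise = 0.05, seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(E * N, 0, 0.2), E, N,
              dimnames = list(NULL, sprintf("s%02d", seq_len(N))))
  list(A = S + matrix(rnorm(E * N, 0, noise), E, N),
       B = S + matrix(rnorm(E * N, 0, noise), E, N),
       S = S)
}
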