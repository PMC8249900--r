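#' Stack paired test/retest edge vectors into a group matrix
#'
#' Builds the E x 2N group edge matrix on which the identifiability
#' decomposition operates: all restA edge vectors first (subject order),
#' then the matched restB vectors.
#'
#' @param fcsA,fcsB the restA and restB connectome sets: lists of
#'   [FunctionalConnectome-class] or E x N matrices whose columns are named
#'   by subject. Both sets must cover the same subjects over the same
#'   parcellation.
#' @param subjectIDs optional subject ids when matrices are unnamed.
#' @return A [GroupEdgeMatrix-class].
#' @examples
#' A <- matrix(runif(30, -1, 1), 10, 3, dimnames = list(NULL, c("s1","s2","s3")))
#' B <- A + rnorm(30, sd = 0.05)
#' colnames(B) <- colnames(A)
#' g <- buildGroupMatrix(A, B)
#' dim(g)  # 10 x 6
#' @export
buildGroupMatrix <- function(fcsA, fcsB, subjectIDs = NULL) {
  A <- .edgeMatrix(fcsA)
  B <- .edgeMatrix(fcsB)
  if (nrow(A) != nrow(B))
    stop("restA and restB edge spaces differ (", nrow(A), " vs ", nrow(B), ")")
  if (is.null(subjectIDs)) {
    subjectIDs <- colnames(A) %||% sprintf("S%03d", seq_len(ncol(A)))
  }
  if (ncol(A) != ncol(B) || ncol(A) != length(subjectIDs))
    stop("restA and restB must contain the same subjects")
  if (!is.null(colnames(A)) && !is.null(colnames(B))) {
    if (!setequal(colnames(A), colnames(B)))
      stop("subject mismatch between restA and restB sets: ",
           paste(symdiff <- union(setdiff(colnames(A), colnames(B)),
                                  setdiff(colnames(B), colnames(A))),
                 collapse = ", "))
    B <- B[, match(colnames(A), colnames(B)), drop = FALSE]
    subjectIDs <- colnames(A)
  }
  N <- length(subjectIDs)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edges = unname(cbind(A, B))),
    colData = S4Vectors::DataFrame(
      subject = rep(subjectIDs, 2L),
      session = rep(c("restA", "restB"), each = N)))
  new("GroupEdgeMatrix", se)
}

#' Group-level PCA of a GroupEdgeMatrix
#'
#' Decomposes the group matrix by singular value decomposition. With
#' `center = TRUE` each edge (row) is centered over the 2N columns first
#' (textbook PCA; at most 2N - 1 components are then non-trivial, and the
#' means are restored by [reconstructAt()]). With `center = FALSE` the raw
#' matrix is decomposed and the grand connectivity pattern is retained as
#' the dominant leading component — this is the mode the identifiability
#' sweep uses (see [sweepIdentifiability()]). Component loadings live in
#' edge space and are orthonormal; each column of the group matrix has a
#' score per component. The sign of each component is fixed by making its
#' largest-magnitude loading entry positive, so results are deterministic
#' across linear-algebra backends.
#'
#' @param group a [GroupEdgeMatrix-class] with at least 2 columns.
#' @param center logical; subtract per-edge means before decomposing
#'   (default `TRUE`).
#' @return A [PCABasis-class] (its `edgeMeans` slot is zero when
#'   `center = FALSE`).
#' @seealso [reconstructAt()], [sweepIdentifiability()]
#' @export
decomposeGroup <- function(group, center = TRUE) {
  stopifnot(is(group, "GroupEdgeMatrix"))
  X <- SummarizedExperiment::assay(group, "edges")
  if (ncol(X) < 2L) stop("need at least 2 columns (one subject, two sessions)")
  if (max(abs(X - rowMeans(X))) == 0)
    stop("group matrix has no variance across columns; PCA undefined")
  mu <- if (center) rowMeans(X) else numeric(nrow(X))
  Xc <- if (center) X - mu else X
  k <- min(dim(X))
  sv <- svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(k), function(c) {
    u <- sv$u[, c]
    sign(u[which.max(abs(u))]) < 0
  }, logical(1))
  U <- sv$u
  U[, flip] <- -U[, flip]
  scores <- d * t(sv$v)             # k x 2N
  scores[flip, ] <- -scores[flip, , drop = FALSE]
  new("PCABasis",
      loadings = U,
      scores = scores,
      edgeMeans = mu,
      explainedVarianceRatio = d^2 / sum(d^2),
      colData = as.data.frame(SummarizedExperiment::colData(group)))
}

#' Reconstruct the group matrix from its first m components
#'
#' Each column is rebuilt as the per-edge means plus the sum of its first m
#' score-weighted loadings. Reconstruction at full rank reproduces the input
#' to numerical precision; truncated reconstruction discards the
#' low-variance directions, which is the denoising step of the
#' identifiability framework.
#'
#' @param basis a [PCABasis-class].
#' @param m number of components to retain, `1 <= m <= ncol(loadings)`.
#' @return A [GroupEdgeMatrix-class] with the original subject/session
#'   bookkeeping.
#' @export
reconstructAt <- function(basis, m) {
  stopifnot(is(basis, "PCABasis"))
  k <- ncol(basis@loadings)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > k)
    stop("m must be a single integer in [1, ", k, "]")
  X <- basis@edgeMeans +
    basis@loadings[, seq_len(m), drop = FALSE] %*%
    basis@scores[seq_len(m), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edges = X),
    colData = S4Vectors::DataFrame(basis@colData))
  new("GroupEdgeMatrix", se)
}

#' Identifiability matrix: cross-session subject similarity
#'
#' The square, non-symmetric N x N matrix whose (i, j) entry is the Pearson
#' correlation between subject i's restA edge vector and subject j's restB
#' edge vector. Its diagonal holds within-subject test/retest similarities;
#' off-diagonal entries hold between-subject similarities.
#'
#' @param fcsA,fcsB restA/restB connectome sets (matrices or lists), same
#'   subject order.
#' @return N x N numeric matrix.
#' @export
identifiabilityMatrix <- function(fcsA, fcsB) {
  A <- .edgeMatrix(fcsA)
  B <- .edgeMatrix(fcsB)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B))
    stop("restA and restB sets must have matching dimensions")
  sdA <- apply(A, 2, sd)
  sdB <- apply(B, 2, sd)
  if (any(sdA == 0) || any(sdB == 0))
    stop("zero-variance edge vector(s); correlations undefined")
  cor(A, B)
}

#' Whole-cohort fingerprint statistics from an identifiability matrix
#'
#' Self-identifiability is the mean of the N diagonal entries (same subject,
#' two sessions); others-identifiability the mean of the N(N-1) off-diagonal
#' entries (different subjects); differential identifiability is 100 times
#' their difference.
#'
#' @param I N x N identifiability matrix, N >= 2.
#' @return List with `iSelf`, `iOthers` (correlation scale) and `iDiff`
#'   (percentage-point scale).
#' @export
identifiabilityScores <- function(I) {
  I <- as.matrix(I)
  N <- nrow(I)
  if (ncol(I) != N) stop("identifiability matrix must be square")
  if (N < 2L)
    stop("need at least 2 subjects: others-identifiability is undefined for N = 1")
  iSelf <- mean(diag(I))
  iOthers <- (sum(I) - sum(diag(I))) / (N * (N - 1))
  list(iSelf = iSelf, iOthers = iOthers, iDiff = 100 * (iSelf - iOthers))
}

#' Reconstruction sweep: find the PC count maximizing differential
#' identifiability
#'
#' Decomposes the group matrix, then for each candidate number of components
#' m reconstructs all connectomes from the first m components and computes
#' the identifiability statistics. The optimum `mStar` is the smallest m
#' maximizing differential identifiability; the connectomes reconstructed at
#' `mStar` are the "optimal" connectomes used downstream.
#'
#' The sweep decomposes without centering by default: the shared grand
#' connectivity pattern is kept as the leading component rather than being
#' removed. The subject-stable subspace of an N-subject two-session stack
#' then has dimension exactly N, which is why differential identifiability
#' peaks at the cohort size on data whose between-subject structure
#' dominates session noise — and it does so for every repetition, not just
#' on average. (With per-edge centering the stable span loses one dimension
#' to the removed mean and the optimum is pulled to N - 1.)
#'
#' @param group a [GroupEdgeMatrix-class].
#' @param mRange integer vector of PC counts to sweep; default `2:k` where k
#'   is the number of components (m = 1 is excluded because correlations
#'   after rank-1 reconstruction can be degenerate).
#' @param center passed to [decomposeGroup()]; default `FALSE` (see above).
#' @return List with `profile` (an [IdentifiabilityProfile-class]) and
#'   `optimal` (the [GroupEdgeMatrix-class] reconstructed at `mStar`).
#' @examples
#' coh <- generateFCCohort(syntheticConfig(nSubjects = 8, nRegions = 20, seed = 7))
#' sw <- sweepIdentifiability(buildGroupMatrix(coh@restA, coh@restB))
#' mStar(sw$profile)  # 8: the cohort size
#' @export
sweepIdentifiability <- function(group, mRange = NULL, center = FALSE) {
  basis <- decomposeGroup(group, center = center)
  k <- ncol(basis@loadings)
  if (is.null(mRange)) mRange <- 2:k
  mRange <- sort(unique(as.integer(mRange)))
  if (any(mRange < 2L) || any(mRange > k))
    stop("mRange must lie within [2, ", k, "]")
  isA <- basis@colData$session == "restA"
  subjA <- basis@colData$subject[isA]
  ordB <- match(subjA, basis@colData$subject[!isA])
  cum <- cumsum(basis@explainedVarianceRatio)
  acc <- matrix(basis@edgeMeans, nrow(basis@loadings), nrow(basis@colData))
  iSelf <- iOthers <- numeric(length(mRange))
  ptr <- 1L
  for (m in seq_len(max(mRange))) {
    acc <- acc + tcrossprod(basis@loadings[, m], basis@scores[m, ])
    if (ptr <= length(mRange) && m == mRange[ptr]) {
      A <- acc[, isA, drop = FALSE]
      B <- acc[, !isA, drop = FALSE][, ordB, drop = FALSE]
      sc <- identifiabilityScores(cor(A, B))
      iSelf[ptr] <- sc$iSelf
      iOthers[ptr] <- sc$iOthers
      ptr <- ptr + 1L
    }
  }
  iDiff <- 100 * (iSelf - iOthers)
  mStar <- mRange[which.max(iDiff)]   # first index: smallest m on ties
  profile <- new("IdentifiabilityProfile",
                 mValues = mRange, iSelf = iSelf, iOthers = iOthers,
                 iDiff = iDiff, cumR2 = cum[mRange], mStar = mStar)
  list(profile = profile, optimal = reconstructAt(basis, mStar))
}

#' Edgewise test/retest reliability: ICC(2,1)
#'
#' For every edge, the Shrout-Fleiss intraclass correlation ICC(2,1)
#' (two-way random effects, absolute agreement, single measure) is computed
#' from the N x 2 subject-by-session table:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)}
#' with k = 2 sessions and n = N subjects, where MSR, MSC and MSE are the
#' row (subject), column (session) and residual mean squares of the two-way
#' ANOVA. Values below 0 are kept as computed; edges with zero total
#' variance get `NA` (undefined), never 0.
#'
#' @param fcsA,fcsB restA/restB connectome sets (matrices or lists) over the
#'   same N >= 2 subjects.
#' @return Numeric vector of length E (`NA` where undefined).
#' @export
edgewiseICC <- function(fcsA, fcsB) {
  A <- .edgeMatrix(fcsA)
  B <- .edgeMatrix(fcsB)
  stopifnot(identical(dim(A), dim(B)))
  N <- ncol(A)
  if (N < 2L) stop("ICC requires at least 2 subjects")
  ri <- (A + B) / 2                       # subject means, per edge
  c1 <- rowMeans(A); c2 <- rowMeans(B)    # session means, per edge
  gm <- (c1 + c2) / 2
  SSR <- 2 * rowSums((ri - gm)^2)
  SSC <- N * ((c1 - gm)^2 + (c2 - gm)^2)
  SST <- rowSums((A - gm)^2) + rowSums((B - gm)^2)
  SSE <- pmax(SST - SSR - SSC, 0)
  MSR <- SSR / (N - 1)
  MSC <- SSC                              # df = k - 1 = 1
  MSE <- SSE / (N - 1)
  icc <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / N)
  icc[SST == 0] <- NA_real_
  icc
}

#' Write an identifiability profile and its optimum to TSV
#'
#' @param profile an [IdentifiabilityProfile-class].
#' @param path output TSV path (columns m, iSelf, iOthers, iDiff, cumR2); a
#'   one-line optimum summary is appended as a `#` comment.
#' @return The profile, invisibly.
#' @export
writeIdentifiabilityProfile <- function(profile, path) {
  df <- as.data.frame(profile)
  names(df)[1] <- "m"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  i <- match(profile@mStar, profile@mValues)
  cat(sprintf("# optimum: m_star=%d iDiff=%.4f cumR2=%.4f\n",
              profile@mStar, profile@iDiff[i], profile@cumR2[i]),
      file = path, append = TRUE)
  invisible(profile)
}
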