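test_that("group matrix stacks restA then restB with matched subjects", {
  co <- toyPairedCohort(N = 5, E = 12)
  g <- buildGroupMatrix(co$A, co$B)
  expect_s4_class(g, "GroupEdgeMatrix")
  expect_equal(dim(g), c(12L, 10L))
  cd <- SummarizedExperiment::colData(g)
  expect_equal(cd$session, rep(c("restA", "restB"), each = 5))
  expect_equal(sessionMatrix(g, "restA"), co$A)
  expect_equal(sessionMatrix(g, "restB"), co$B)

  # subject alignment happens by name even when column order differs
  g2 <- buildGroupMatrix(co$A, co$B[, rev(colnames(co$B))])
  expect_equal(sessionMatrix(g2, "restB"), co$B)

  expect_error(buildGroupMatrix(co$A, co$B[, 1:4]), "same subjects")
  B2 <- co$B; colnames(B2)[1] <- "sXX"
  expect_error(buildGroupMatrix(co$A, B2), "mismatch")

  # minimal cohort: one subject, two columns
  g1 <- buildGroupMatrix(co$A[, 1, drop = FALSE], co$B[, 1, drop = FALSE])
  expect_equal(ncol(g1), 2L)
})

test_that("centered decomposition recovers rank-1 structure exactly", {
  set.seed(4)
  pattern <- rnorm(30)
  mu <- rnorm(30)
  scal <- rnorm(8)
  X <- mu + outer(pattern, scal)
  X <- X - rowMeans(X) + rowMeans(X)      # no-op, keep as built
  A <- X[, 1:4]; B <- X[, 5:8]
  colnames(A) <- colnames(B) <- paste0("s", 1:4)
  b <- decomposeGroup(buildGroupMatrix(A, B))
  expect_equal(b@explainedVarianceRatio[1], 1, tolerance = 1e-10)
  r1 <- SummarizedExperiment::assay(reconstructAt(b, 1), "edges")
  expect_equal(unname(r1), unname(cbind(A, B)), tolerance = 1e-8)
})

test_that("decomposition properties hold in both centering modes", {
  co <- toyPairedCohort(N = 6, E = 40, seed = 2)
  g <- buildGroupMatrix(co$A, co$B)
  for (center in c(TRUE, FALSE)) {
    b <- decomposeGroup(g, center = center)
    evr <- b@explainedVarianceRatio
    expect_equal(sum(evr), 1, tolerance = 1e-12)
    expect_true(all(diff(evr) <= 1e-12))
    # full-rank reconstruction reproduces the input
    full <- SummarizedExperiment::assay(reconstructAt(b, ncol(b@loadings)), "edges")
    expect_equal(unname(full), unname(cbind(co$A, co$B)), tolerance = 1e-10)
    # orthonormal loadings, deterministic sign
    expect_equal(crossprod(b@loadings), diag(ncol(b@loadings)), tolerance = 1e-8)
    for (c in seq_len(ncol(b@loadings))) {
      u <- b@loadings[, c]
      expect_gt(u[which.max(abs(u))], 0)
    }
  }
  const <- matrix(0.5, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(decomposeGroup(buildGroupMatrix(const, const)), "no variance")
})

test_that("truncated reconstructions have nested residuals", {
  co <- toyPairedCohort(N = 6, E = 40, seed = 9)
  g <- buildGroupMatrix(co$A, co$B)
  b <- decomposeGroup(g)
  X <- cbind(co$A, co$B)
  res <- vapply(1:ncol(b@loadings), function(m) {
    sqrt(sum((SummarizedExperiment::assay(reconstructAt(b, m), "edges") - X)^2))
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
  expect_error(reconstructAt(b, 0), "m must be")
  expect_error(reconstructAt(b, ncol(b@loadings) + 1L), "m must be")
})

test_that("identifiability matrix holds all cross-session correlations", {
  # two hand-computable subjects over 3 edges
  r <- 9 / (2 * sqrt(21))   # cor([1,2,3],[1,2,4])
  A <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  B <- cbind(s1 = c(1, 2, 4), s2 = c(4, 2, 1))
  I <- identifiabilityMatrix(A, B)
  expect_equal(I, matrix(c(r, -r, -r, r), 2, 2,
                         dimnames = list(c("s1", "s2"), c("s1", "s2"))),
               tolerance = 1e-12)
  expect_equal(round(r, 4), 0.9820)

  co <- toyPairedCohort(N = 5, E = 30)
  expect_equal(diag(identifiabilityMatrix(co$A, co$A)), rep(1, 5),
               ignore_attr = TRUE)
  expect_equal(dim(identifiabilityMatrix(co$A[, 1, drop = FALSE],
                                         co$B[, 1, drop = FALSE])), c(1L, 1L))
  Z <- co$A; Z[, 2] <- 0.3
  expect_error(identifiabilityMatrix(Z, co$B), "zero-variance")
})

test_that("identifiability scores are the diagonal/off-diagonal means", {
  expect_equal(identifiabilityScores(matrix(1, 3, 3)),
               list(iSelf = 1, iOthers = 1, iDiff = 0))
  expect_equal(identifiabilityScores(diag(4)),
               list(iSelf = 1, iOthers = 0, iDiff = 100))
  r <- 9 / (2 * sqrt(21))
  sc <- identifiabilityScores(matrix(c(r, -r, -r, r), 2, 2))
  expect_equal(sc$iSelf, r, tolerance = 1e-12)
  expect_equal(sc$iOthers, -r, tolerance = 1e-12)
  expect_equal(sc$iDiff, 196.4, tolerance = 1e-3)
  expect_error(identifiabilityScores(matrix(1, 1, 1)), "N = 1")

  # the x100 identity holds for arbitrary matrices
  set.seed(11)
  for (i in 1:5) {
    I <- matrix(runif(25, -1, 1), 5, 5)
    s <- identifiabilityScores(I)
    expect_equal(s$iDiff, 100 * (s$iSelf - s$iOthers))
  }
})

test_that("the sweep picks the smallest argmax and matches full-rank identity", {
  co <- toyPairedCohort(N = 6, E = 50, noise = 0.1, seed = 5)
  g <- buildGroupMatrix(co$A, co$B)
  sw <- sweepIdentifiability(g)
  p <- sw$profile
  expect_equal(p@iDiff, 100 * (p@iSelf - p@iOthers), tolerance = 1e-10)
  expect_true(all(diff(p@cumR2) >= -1e-12))
  expect_equal(p@cumR2[length(p@cumR2)], 1, tolerance = 1e-10)
  # at full rank the scores equal those on the raw connectomes
  direct <- identifiabilityScores(identifiabilityMatrix(co$A, co$B))
  k <- max(p@mValues)
  expect_equal(p@iDiff[match(k, p@mValues)], direct$iDiff, tolerance = 1e-6)
  # argmax property: no swept m beats m*
  expect_true(all(p@iDiff <= p@iDiff[match(p@mStar, p@mValues)]))
  expect_gte(p@iDiff[match(p@mStar, p@mValues)], p@iDiff[match(k, p@mValues)])
  expect_error(sweepIdentifiability(g, mRange = c(1, 3)), "mRange")

  # ties resolve to the smallest m: duplicate an m via a degenerate range
  expect_equal(mStar(sweepIdentifiability(g, mRange = c(4, 4))$profile), 4L)
})

test_that("differential identifiability peaks at the cohort size", {
  for (s in 1:3) {
    coh <- generateFCCohort(syntheticConfig(nSubjects = 12, nRegions = 30,
                                            seed = s))
    sw <- sweepIdentifiability(buildGroupMatrix(coh@restA, coh@restB))
    expect_equal(mStar(sw$profile), 12L)
  }
})

test_that("optimal reconstruction improves edgewise ICC over full rank", {
  coh <- generateFCCohort(syntheticConfig(nSubjects = 12, nRegions = 30,
                                          seed = 21))
  sw <- sweepIdentifiability(buildGroupMatrix(coh@restA, coh@restB))
  iccFull <- edgewiseICC(coh@restA, coh@restB)
  iccOpt <- edgewiseICC(sessionMatrix(sw$optimal, "restA"),
                        sessionMatrix(sw$optimal, "restB"))
  expect_gt(mean(iccOpt, na.rm = TRUE), mean(iccFull, na.rm = TRUE))
})

test_that("edgewise ICC(2,1) matches the two-way ANOVA oracle", {
  # perfect agreement with between-subject spread
  A <- rbind(e1 = c(1, 2, 3, 4))
  expect_equal(unname(edgewiseICC(A, A)), 1)

  # hand case: subjects x sessions [[1,2],[2,3],[3,4]] -> ICC = 2/3
  a <- matrix(c(1, 2, 3), 1); b <- matrix(c(2, 3, 4), 1)
  expect_equal(edgewiseICC(a, b), 2 / 3, tolerance = 1e-12)

  # independent oracle: mean squares from stats::aov, Shrout-Fleiss formula
  iccAOV <- function(x, y) {
    n <- length(x)
    d <- data.frame(val = c(x, y),
                    subj = factor(rep(seq_len(n), 2)),
                    sess = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(val ~ subj + sess, data = d))[[1]][, "Mean Sq"]
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / n)
  }
  expect_equal(iccAOV(c(1, 2, 3), c(2, 3, 4)), 2 / 3, tolerance = 1e-12)
  set.seed(8)
  A <- matrix(rnorm(5 * 9), 5, 9)
  B <- A + matrix(rnorm(5 * 9, 0.1, 0.3), 5, 9)
  got <- edgewiseICC(A, B)
  want <- vapply(1:5, function(e) iccAOV(A[e, ], B[e, ]), numeric(1))
  expect_equal(got, want, tolerance = 1e-10)

  # zero-variance edge is undefined, not zero
  Z <- matrix(1, 2, 6); Z[2, ] <- rnorm(6)
  out <- edgewiseICC(Z, Z)
  expect_true(is.na(out[1]))
  expect_equal(out[2], 1)
})

test_that("ICC of independent sessions is centered on zero", {
  set.seed(12)
  E <- 200; N <- 500
  A <- matrix(rnorm(E * N), E, N)
  B <- matrix(rnorm(E * N), E, N)
  expect_lt(abs(mean(edgewiseICC(A, B))), 0.05)
})

test_that("profile serialization writes the sweep and its optimum", {
  co <- toyPairedCohort(N = 5, E = 30)
  p <- sweepIdentifiability(buildGroupMatrix(co$A, co$B))$profile
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIdentifiabilityProfile(p, path)
  d <- read.delim(path, comment.char = "#")
  expect_equal(d$m, p@mValues)
  expect_equal(d$iDiff, p@iDiff, tolerance = 1e-6)
  expect_match(readLines(path)[length(readLines(path))], "m_star=")
})
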