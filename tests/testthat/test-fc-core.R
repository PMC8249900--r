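test_that("half split gives contiguous blocks with the extra frame first", {
  ts140 <- regionalTimeSeries(matrix(rnorm(140 * 4), 140, 4), "s1")
  halves <- splitTimeSeries(ts140, "half")
  expect_equal(nrow(tsValues(halves[[1]])), 70)
  expect_equal(nrow(tsValues(halves[[2]])), 70)

  ts5 <- regionalTimeSeries(matrix(rnorm(5 * 4), 5, 4), "s1")
  h5 <- splitTimeSeries(ts5, "half")
  expect_equal(nrow(tsValues(h5[[1]])), 3)
  expect_equal(nrow(tsValues(h5[[2]])), 2)
  expect_equal(tsValues(h5[[1]]), tsValues(ts5)[1:3, ])

  expect_error(splitTimeSeries(
    regionalTimeSeries(matrix(rnorm(6), 3, 2), "s1"), "half"), "degenerate")
})

test_that("interleaved split takes frame parity and doubles the TR", {
  v <- matrix(seq_len(16), 4, 4,  # frames f0..f3 in rows
              dimnames = list(NULL, sprintf("R%03d", 1:4)))
  ts <- regionalTimeSeries(v, "s1", repetitionTime = 3)
  halves <- splitTimeSeries(ts, "interleaved")
  expect_equal(tsValues(halves[[1]]), v[c(1, 3), ])
  expect_equal(tsValues(halves[[2]]), v[c(2, 4), ])
  expect_equal(halves[[1]]@repetitionTime, 6)
  expect_equal(halves[[2]]@repetitionTime, 6)
  # half mode keeps the TR
  expect_equal(splitTimeSeries(ts, "half")[[1]]@repetitionTime, 3)
})

test_that("both split modes partition the frames and the censor mask", {
  for (T in c(4, 7, 11, 20)) {
    cm <- runif(T) < 0.3
    ts <- regionalTimeSeries(matrix(rnorm(T * 3), T, 3), "s1", censorMask = cm)
    for (mode in c("half", "interleaved")) {
      h <- splitTimeSeries(ts, mode)
      expect_equal(nrow(tsValues(h[[1]])) + nrow(tsValues(h[[2]])), T)
      expect_equal(sum(h[[1]]@censorMask) + sum(h[[2]]@censorMask), sum(cm))
      # every frame appears exactly once across the two halves
      allRows <- rbind(tsValues(h[[1]]), tsValues(h[[2]]))
      expect_equal(allRows[order(allRows[, 1]), ],
                   tsValues(ts)[order(tsValues(ts)[, 1]), ])
    }
  }
})

test_that("session labels are a seeded per-subject coin flip", {
  mk <- function(sid) {
    ts <- regionalTimeSeries(matrix(rnorm(32), 8, 4), sid)
    splitTimeSeries(ts, "half")
  }
  h <- mk("subjA")
  p1 <- assignSessionLabels(h[[1]], h[[2]], seed = 7)
  p2 <- assignSessionLabels(h[[1]], h[[2]], seed = 7)
  expect_identical(lapply(p1, tsValues), lapply(p2, tsValues))
  expect_setequal(vapply(p1, sessionLabel, ""), c("restA", "restB"))

  # over many subjects, some flips differ between two seeds
  flips <- function(seed) vapply(sprintf("sub%03d", 1:40), function(sid) {
    h <- mk(sid)
    sessionLabel(assignSessionLabels(h[[1]], h[[2]], seed)[[1]]) == "restA" &&
      identical(tsValues(assignSessionLabels(h[[1]], h[[2]], seed)[[1]]),
                tsValues(h[[1]]))
  }, logical(1))
  expect_true(any(flips(1) != flips(2)))
  expect_true(any(flips(1)) && !all(flips(1)))  # both labelings occur

  hB <- mk("subjB")
  expect_error(assignSessionLabels(h[[1]], hB[[2]], seed = 1), "different subjects")
})

test_that("censor filter excludes strictly above 30% censored frames", {
  mk <- function(sid, nCens) {
    cm <- rep(FALSE, 140); cm[seq_len(nCens)] <- TRUE
    regionalTimeSeries(matrix(rnorm(140 * 3), 140, 3), sid, censorMask = cm)
  }
  noMask <- regionalTimeSeries(matrix(rnorm(140 * 3), 140, 3), "s3")
  res <- applyCensorFilter(list(mk("s1", 43), mk("s2", 42), noMask))
  expect_equal(vapply(res$kept, subjectID, ""), c("s2", "s3"))
  expect_equal(res$excluded$subject, "s1")
  expect_equal(res$excluded$fraction, 43 / 140)
  expect_equal(applyCensorFilter(list())$kept, list())
})

test_that("connectome is the Pearson correlation of uncensored frames", {
  x <- rnorm(20)
  v <- cbind(r1 = x, r2 = x, r3 = -x + rnorm(20, 0, 1e-12), r4 = rnorm(20))
  fc <- computeConnectome(regionalTimeSeries(v, "s1"))
  m <- fcMatrix(fc)
  expect_equal(m["r1", "r2"], 1)
  expect_equal(m["r1", "r3"], -1, tolerance = 1e-6)
  expect_equal(diag(m), setNames(rep(1, 4), colnames(v)))

  # hand-computed 3-point correlation: cor([1,2,3],[1,2,4]) = 9/(2*sqrt(21))
  v2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
  fc2 <- computeConnectome(regionalTimeSeries(v2, "s1"))
  expect_equal(fcMatrix(fc2)["a", "b"], 9 / (2 * sqrt(21)), tolerance = 1e-12)

  # censored frames are deleted before correlating
  v3 <- rbind(v2, c(100, -100))
  cm <- c(FALSE, FALSE, FALSE, TRUE)
  fc3 <- computeConnectome(regionalTimeSeries(v3, "s1", censorMask = cm))
  expect_equal(fcMatrix(fc3)["a", "b"], 9 / (2 * sqrt(21)), tolerance = 1e-12)
})

test_that("connectome is invariant to affine rescaling of a region", {
  set.seed(3)
  v <- matrix(rnorm(60), 20, 3)
  base <- fcMatrix(computeConnectome(regionalTimeSeries(v, "s")))
  v2 <- v; v2[, 2] <- 5 * v2[, 2] - 7
  scaled <- fcMatrix(computeConnectome(regionalTimeSeries(v2, "s")))
  expect_equal(unname(base), unname(scaled), tolerance = 1e-12)
})

test_that("degenerate connectome inputs fail loudly", {
  v <- cbind(r1 = rnorm(10), flat = rep(2, 10))
  expect_error(computeConnectome(regionalTimeSeries(v, "s1")), "flat")
  ts <- regionalTimeSeries(matrix(rnorm(8), 4, 2), "s1",
                           censorMask = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(computeConnectome(ts), "fewer than 3")
})

test_that("edge vectorization uses row-major upper-triangle order", {
  m <- toyMatrix(c(0.1, 0.2, 0.3), 3)
  expect_equal(vectorizeConnectome(m), c(0.1, 0.2, 0.3))
  # R = 4 distinguishes row-major from column-major order
  m4 <- matrix(1, 4, 4)
  vals <- c(12, 13, 14, 23, 24, 34)
  m4[lower.tri(m4)] <- 0; m4 <- t(m4)
  k <- 0
  for (i in 1:3) for (j in (i + 1):4) { k <- k + 1; m4[i, j] <- vals[k]; m4[j, i] <- vals[k] }
  expect_equal(vectorizeConnectome(m4), vals)

  set.seed(1)
  for (R in c(3, 7, 12)) {
    vec <- runif(edgeCount(R), -1, 1)
    m <- devectorizeEdges(vec, R)
    expect_true(isSymmetric(m))
    expect_equal(diag(m), rep(1, R))
    expect_identical(vectorizeConnectome(m), vec)  # exact round trip
  }
  expect_error(devectorizeEdges(1:5, 4), "expected R\\(R-1\\)/2")
})

test_that("edge counts follow E = R(R-1)/2", {
  expect_identical(edgeCount(3), 3L)
  expect_identical(edgeCount(10), 45L)
  expect_identical(edgeCount(286), 40755L)
  for (R in c(3, 10, 286))
    expect_equal(nrow(edgeIndex(R)), edgeCount(R))
})

test_that("edge index is a bijection with RSN pairs partitioning the edges", {
  parc <- makeSyntheticParcellation(27)
  ei <- edgeIndex(parc)
  expect_true(all(ei$i < ei$j))
  expect_false(anyDuplicated(ei[, c("i", "j")]) > 0)
  expect_equal(nrow(ei), edgeCount(27))
  # 9 networks -> 45 unordered pairs; every edge has exactly one
  expect_length(rsnPairLabels(), 45L)
  expect_equal(nlevels(ei$rsnPair), 45L)
  expect_false(anyNA(ei$rsnPair))
  expect_equal(sum(table(ei$rsnPair)), edgeCount(27))
})

test_that("text formats round-trip through their readers and writers", {
  dir <- withr::local_tempdir()
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("ROI1", "ROI2", "ROI3", "ROI4")))
  cm <- c(rep(FALSE, 8), TRUE, TRUE)
  ts <- regionalTimeSeries(v, "s1", censorMask = cm)
  writeTimeSeries(ts, file.path(dir, "ts.tsv"), file.path(dir, "ts.censor"))
  ts2 <- readTimeSeries(file.path(dir, "ts.tsv"), "s1",
                        censorPath = file.path(dir, "ts.censor"))
  expect_equal(tsValues(ts2), v, tolerance = 1e-12)
  expect_equal(ts2@censorMask, cm)

  fc <- computeConnectome(regionalTimeSeries(matrix(rnorm(60), 20, 3), "s2"))
  writeConnectome(fc, file.path(dir, "fc.tsv"))
  fc2 <- readConnectome(file.path(dir, "fc.tsv"), "s2")
  expect_equal(unname(fcMatrix(fc2)), unname(fcMatrix(fc)), tolerance = 1e-12)

  parc <- makeSyntheticParcellation(12)
  writeParcellation(parc, file.path(dir, "parc.tsv"))
  parc2 <- readParcellation(file.path(dir, "parc.tsv"))
  expect_equal(regionIDs(parc2), regionIDs(parc))
  expect_equal(rsnLabels(parc2), rsnLabels(parc))
  expect_equal(regionCoordinates(parc2), regionCoordinates(parc),
               ignore_attr = TRUE, tolerance = 1e-9)

  vec <- round(runif(edgeCount(12), -1, 1), 6)
  writeEdgeVector(vec, parc, file.path(dir, "edges.tsv"))
  expect_equal(unname(readEdgeVector(file.path(dir, "edges.tsv"))), vec)

  out <- data.frame(subject = c("a", "b"), moca = c(25, 28))
  writeOutcomeTable(out, file.path(dir, "out.tsv"))
  expect_equal(readOutcomeTable(file.path(dir, "out.tsv")), out)
})
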