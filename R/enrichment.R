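#' Consensus mask across cross-validation repetitions
#'
#' An edge enters the consensus mask for a sign if it was selected with that
#' sign in at least `ceiling(freq * nReps)` repetitions (at least one when
#' `freq = 0`, which reduces to the union of all masks). With the default
#' `freq = 0.95` over 1000 repetitions an edge needs 950 selections.
#'
#' @param maskStack list of per-repetition [EdgeMask-class] objects over a
#'   common edge space (NULL entries, e.g. failed repetitions, are dropped).
#' @param freq required selection frequency in \[0, 1\], default 0.95.
#' @return An [EdgeMask-class]; attributes `freq`, `nReps` and the per-edge
#'   selection counts `countsPos`, `countsNeg` are attached.
#' @export
consensusMask <- function(maskStack, freq = 0.95) {
  maskStack <- Filter(Negate(is.null), maskStack)
  if (!length(maskStack)) stop("need at least one repetition mask")
  nReps <- length(maskStack)
  cntP <- Reduce(`+`, lapply(maskStack, function(m) as.integer(m@positive)))
  cntN <- Reduce(`+`, lapply(maskStack, function(m) as.integer(m@negative)))
  need <- max(ceiling(freq * nReps), 1L)
  out <- edgeMask(cntP >= need, cntN >= need,
                  threshold = maskStack[[1]]@threshold,
                  outcome = maskStack[[1]]@outcome)
  attr(out, "freq") <- freq
  attr(out, "nReps") <- nReps
  attr(out, "countsPos") <- cntP
  attr(out, "countsNeg") <- cntN
  out
}

# exact upper binomial tail P(X >= k), X ~ Binomial(n, p0)
.binomTail <- function(k, n, p0) {
  if (k <= 0) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Binomial over-representation of RSN pairs in a consensus mask
#'
#' For each of the 45 resting-state-network pairs, tests whether the mask
#' contains more edges from that pair than expected if the same number of
#' edges had been drawn uniformly from the full edge space. With t_P of the
#' E edges belonging to pair P and k of the n mask edges observed in P, the
#' one-sided p-value is P(X >= k) for X ~ Binomial(n, t_P / E). Positive and
#' negative masks are tested separately; no correction is applied across the
#' 45 pairs.
#'
#' @param mask an [EdgeMask-class] (typically from [consensusMask()]).
#' @param edgeIdx the edge index data.frame from [edgeIndex()] on a labeled
#'   parcellation.
#' @param alpha significance level, default 0.05.
#' @return data.frame with one row per (sign, RSN pair): `outcome`, `sign`,
#'   `pair`, `tP` (pair's edge count), `n` (mask size), `k` (observed),
#'   `p0`, `p`, `significant`. For an empty mask side all p are 1 and the
#'   rows are flagged `emptyMask = TRUE`.
#' @export
binomialEnrichment <- function(mask, edgeIdx, alpha = 0.05) {
  if (!"rsnPair" %in% names(edgeIdx))
    stop("edge index lacks RSN pair labels; build it from a labeled Parcellation")
  if (nrow(edgeIdx) != length(mask@positive))
    stop("edge-space mismatch between mask and edge index")
  E <- nrow(edgeIdx)
  tP <- table(edgeIdx$rsnPair)
  pairs <- names(tP)
  res <- lapply(c(positive = "positive", negative = "negative"), function(sgn) {
    sel <- slot(mask, sgn)
    n <- sum(sel)
    k <- as.integer(table(edgeIdx$rsnPair[sel]))
    p0 <- as.numeric(tP) / E
    p <- if (n == 0) rep(1, length(pairs)) else
      vapply(seq_along(pairs), function(i) .binomTail(k[i], n, p0[i]),
             numeric(1))
    data.frame(outcome = mask@outcome, sign = sgn, pair = pairs,
               tP = as.integer(tP), n = n, k = k, p0 = p0, p = p,
               significant = p < alpha & n > 0, emptyMask = n == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Export a mask for BrainNet Viewer
#'
#' Writes the whitespace-delimited `.node` and `.edge` files consumed by
#' BrainNet Viewer. Node columns are x, y, z (mm), a color index (the
#' region's RSN, numbered along [RSN_LEVELS]), a size (the node's degree
#' within the exported edges) and the region label. The edge file is the
#' full symmetric R x R 0/1 matrix. Positive and negative mask sides are
#' written to separate file pairs (`<prefix>_positive.node/.edge`, likewise
#' `negative`).
#'
#' @param mask an [EdgeMask-class].
#' @param parc a [Parcellation-class] with coordinates.
#' @param prefix output path prefix.
#' @param restrictToPairs optional character vector of RSN pair labels (e.g.
#'   from the significant rows of [binomialEnrichment()]); edges outside
#'   these pairs are dropped before export.
#' @return Invisibly, the vector of files written.
#' @export
exportBrainNet <- function(mask, parc, prefix, restrictToPairs = NULL) {
  stopifnot(is(parc, "Parcellation"))
  if (!nrow(parc@coordinates))
    stop("parcellation has no coordinates; cannot export node file")
  ei <- edgeIndex(parc)
  R <- length(parc@regionIDs)
  written <- character(0)
  for (sgn in c("positive", "negative")) {
    sel <- slot(mask, sgn)
    if (!is.null(restrictToPairs))
      sel <- sel & ei$rsnPair %in% restrictToPairs
    adj <- matrix(0L, R, R)
    idx <- cbind(ei$i[sel], ei$j[sel])
    adj[idx] <- 1L
    adj[idx[, 2:1, drop = FALSE]] <- 1L
    degree <- rowSums(adj)
    node <- data.frame(
      x = parc@coordinates[, 1], y = parc@coordinates[, 2],
      z = parc@coordinates[, 3],
      color = match(parc@rsnLabels, RSN_LEVELS),
      size = degree, label = parc@regionIDs)
    nodePath <- paste0(prefix, "_", sgn, ".node")
    edgePath <- paste0(prefix, "_", sgn, ".edge")
    write.table(node, nodePath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(adj, edgePath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, nodePath, edgePath)
  }
  invisible(written)
}
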