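#' Number of unique edges for a given region count
#'
#' A connectome over R regions has E = R(R-1)/2 unique off-diagonal edges
#' (the upper triangle of the symmetric correlation matrix).
#'
#' @param nRegions integer number of regions (>= 2).
#' @return Integer edge count.
#' @examples
#' edgeCount(286)  # 40755
#' @export
edgeCount <- function(nRegions) {
  nRegions <- as.integer(nRegions)
  stopifnot(nRegions >= 2L)
  (nRegions * (nRegions - 1L)) %/% 2L
}

#' Vectorize a connectome to its canonical edge vector
#'
#' Extracts the upper triangle (excluding the diagonal) in row-major order:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). This single canonical
#' order is shared by every module; edge vectors, masks and group matrices
#' are only comparable when built over the same [Parcellation-class] region
#' order.
#'
#' @param fc a [FunctionalConnectome-class] or a symmetric numeric matrix.
#' @return Numeric vector of length R(R-1)/2.
#' @seealso [devectorizeEdges()], [edgeIndex()]
#' @export
vectorizeConnectome <- function(fc) {
  m <- if (is(fc, "FunctionalConnectome")) fc@matrix else as.matrix(fc)
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorizeConnectome()]: places the edge values back into the
#' upper and lower triangles (row-major upper-triangle order) and sets the
#' diagonal to 1.
#'
#' @param vec numeric edge vector of length R(R-1)/2.
#' @param nRegions the region count R.
#' @return Symmetric R x R numeric matrix with unit diagonal.
#' @export
devectorizeEdges <- function(vec, nRegions) {
  nRegions <- as.integer(nRegions)
  E <- edgeCount(nRegions)
  if (length(vec) != E)
    stop(sprintf("edge vector has length %d, expected R(R-1)/2 = %d for R = %d",
                 length(vec), E, nRegions))
  tm <- matrix(0, nRegions, nRegions)
  tm[lower.tri(tm)] <- vec          # fills the transpose's lower triangle,
  m <- t(tm) + tm                   # i.e. the row-major upper triangle
  diag(m) <- 1
  m
}

#' Edge index: map edge ids to region pairs and RSN-pair labels
#'
#' Enumerates the canonical edge order of a parcellation. Each edge (i, j)
#' with i < j is assigned the unordered pair of its two regions' RSN labels,
#' written `"A-B"` with A before B in the canonical [RSN_LEVELS] order. For
#' 9 networks there are exactly 45 distinct pair labels (9 within-network
#' plus 36 between-network).
#'
#' @param parc a [Parcellation-class], or an integer region count (in which
#'   case RSN pair labels are omitted).
#' @return data.frame with columns `edge`, `i`, `j`, `regionI`, `regionJ`
#'   and, when labels are available, `rsnPair` (a factor over all 45 levels).
#' @examples
#' p <- makeSyntheticParcellation(9)
#' nlevels(edgeIndex(p)$rsnPair)  # 45
#' @export
edgeIndex <- function(parc) {
  if (is.numeric(parc)) {
    R <- as.integer(parc)
    ids <- sprintf("R%03d", seq_len(R))
    labs <- NULL
  } else {
    stopifnot(is(parc, "Parcellation"))
    R <- length(parc@regionIDs)
    ids <- parc@regionIDs
    labs <- parc@rsnLabels
  }
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- sequence((R - 1L):1L) + i
  out <- data.frame(edge = seq_along(i), i = i, j = j,
                    regionI = ids[i], regionJ = ids[j],
                    stringsAsFactors = FALSE)
  if (!is.null(labs)) {
    li <- match(labs[i], RSN_LEVELS)
    lj <- match(labs[j], RSN_LEVELS)
    a <- pmin(li, lj); b <- pmax(li, lj)
    out$rsnPair <- factor(paste(RSN_LEVELS[a], RSN_LEVELS[b], sep = "-"),
                          levels = rsnPairLabels())
  }
  out
}

#' All unordered RSN-pair labels
#'
#' @param levels RSN label set, default [RSN_LEVELS].
#' @return Character vector of `choose(k, 2) + k` pair labels `"A-B"` (A at
#'   or before B in canonical order); 45 labels for the default 9 networks.
#' @export
rsnPairLabels <- function(levels = RSN_LEVELS) {
  k <- length(levels)
  idx <- cbind(rep(seq_len(k), times = k:1),
               sequence(k:1) + rep(seq_len(k), times = k:1) - 1L)
  paste(levels[idx[, 1]], levels[idx[, 2]], sep = "-")
}
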