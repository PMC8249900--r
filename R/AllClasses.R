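#' @import methods
#' @importFrom stats cor sd pbinom dbinom lm.fit rnorm runif setNames quantile
#' @importFrom utils read.delim write.table head combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' Resting-state network labels
#'
#' Canonical ordering of the nine resting-state network (RSN) labels used for
#' region assignment: the seven cortical networks (visual, somato-motor,
#' dorsal attention, salience/ventral attention, limbic, executive control,
#' default mode) plus subcortical and cerebellar groups.
#'
#' @format Character vector of length 9.
#' @export
RSN_LEVELS <- c("VIS", "SM", "DA", "SAL", "L", "EC", "DMN", "SUB", "CER")

.SESSION_LEVELS <- c("full", "restA", "restB", "half1", "half2")

#' RegionalTimeSeries: parcellated BOLD time series for one subject/session
#'
#' Holds a T x R matrix of regional BOLD signals (T timepoints, R regions),
#' the repetition time in seconds, and an optional frame censor mask
#' (TRUE = frame flagged for removal, e.g. by motion scrubbing upstream).
#'
#' @slot subjectID character scalar.
#' @slot sessionLabel one of `"full"`, `"restA"`, `"restB"`, or the
#'   provisional `"half1"`/`"half2"` produced by [splitTimeSeries()] before
#'   random session assignment.
#' @slot values numeric matrix, T x R, column names are region ids.
#' @slot repetitionTime numeric scalar, seconds.
#' @slot censorMask logical vector of length T, or `logical(0)` when absent.
#'
#' @seealso [regionalTimeSeries()], [splitTimeSeries()], [computeConnectome()]
#' @export
setClass("RegionalTimeSeries",
  slots = c(
    subjectID = "character",
    sessionLabel = "character",
    values = "matrix",
    repetitionTime = "numeric",
    censorMask = "logical"
  )
)

setValidity("RegionalTimeSeries", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 timepoints")
  if (ncol(v) < 2L) msg <- c(msg, "need at least 2 regions")
  if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be a scalar")
  if (!object@sessionLabel %in% .SESSION_LEVELS)
    msg <- c(msg, sprintf("sessionLabel must be one of %s",
                          paste(.SESSION_LEVELS, collapse = ", ")))
  if (length(object@censorMask) &&
      length(object@censorMask) != nrow(v))
    msg <- c(msg, "censorMask must have one entry per timepoint")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionalTimeSeries
#'
#' @param values numeric T x R matrix (timepoints x regions); column names,
#'   if present, are taken as region ids.
#' @param subjectID subject identifier.
#' @param sessionLabel session label, default `"full"`.
#' @param repetitionTime TR in seconds.
#' @param censorMask optional logical vector of length T; `TRUE` marks a
#'   censored frame.
#' @return A [RegionalTimeSeries-class] object.
#' @examples
#' ts <- regionalTimeSeries(matrix(rnorm(40), 10, 4), "sub01")
#' dim(tsValues(ts))
#' @export
regionalTimeSeries <- function(values, subjectID, sessionLabel = "full",
                               repetitionTime = 3, censorMask = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("R%03d", seq_len(ncol(values)))
  new("RegionalTimeSeries",
      subjectID = as.character(subjectID),
      sessionLabel = sessionLabel,
      values = values,
      repetitionTime = as.numeric(repetitionTime),
      censorMask = if (is.null(censorMask)) logical(0) else as.logical(censorMask))
}

#' Parcellation: region ids, RSN labels and optional coordinates
#'
#' The region order in a `Parcellation` is the single canonical order for all
#' connectome matrices and edge vectors in a workflow. Every region carries
#' exactly one resting-state-network label from [RSN_LEVELS]; MNI coordinates
#' (mm) are optional and only needed for brain-network export.
#'
#' @slot regionIDs character vector, length R, unique.
#' @slot rsnLabels character vector, length R, values in [RSN_LEVELS].
#' @slot coordinates numeric R x 3 matrix (x, y, z in mm) or a 0-row matrix
#'   when coordinates are unavailable.
#' @seealso [parcellation()], [edgeIndex()], [exportBrainNet()]
#' @export
setClass("Parcellation",
  slots = c(regionIDs = "character", rsnLabels = "character",
            coordinates = "matrix")
)

setValidity("Parcellation", function(object) {
  msg <- character()
  R <- length(object@regionIDs)
  if (anyDuplicated(object@regionIDs)) msg <- c(msg, "region ids must be unique")
  if (length(object@rsnLabels) != R)
    msg <- c(msg, "one RSN label per region required")
  bad <- setdiff(unique(object@rsnLabels), RSN_LEVELS)
  if (length(bad))
    msg <- c(msg, sprintf("unknown RSN label(s): %s", paste(bad, collapse = ", ")))
  if (nrow(object@coordinates) && nrow(object@coordinates) != R)
    msg <- c(msg, "coordinates must have one row per region")
  if (nrow(object@coordinates) && ncol(object@coordinates) != 3L)
    msg <- c(msg, "coordinates must have 3 columns (x, y, z)")
  if (length(msg)) msg else TRUE
})

#' Construct a Parcellation
#'
#' @param regionIDs character vector of unique region identifiers; their order
#'   fixes the canonical region order.
#' @param rsnLabels resting-state-network label per region (see [RSN_LEVELS]).
#' @param coordinates optional R x 3 numeric matrix of region coordinates (mm).
#' @return A [Parcellation-class] object.
#' @export
parcellation <- function(regionIDs, rsnLabels, coordinates = NULL) {
  new("Parcellation",
      regionIDs = as.character(regionIDs),
      rsnLabels = as.character(rsnLabels),
      coordinates = if (is.null(coordinates)) matrix(numeric(0), 0, 3)
                    else as.matrix(coordinates))
}

#' FunctionalConnectome: one subject/session correlation matrix
#'
#' A symmetric R x R matrix of pairwise Pearson correlations between regional
#' BOLD time series, with unit diagonal and entries in \[-1, 1\]. The
#' canonical edge vector (length R(R-1)/2, row-major upper triangle) is
#' available through [edgeVector()].
#'
#' @slot subjectID character scalar.
#' @slot sessionLabel session label.
#' @slot matrix symmetric numeric R x R matrix, diagonal 1.
#' @seealso [computeConnectome()], [edgeVector()], [devectorizeEdges()]
#' @export
setClass("FunctionalConnectome",
  slots = c(subjectID = "character", sessionLabel = "character",
            matrix = "matrix")
)

setValidity("FunctionalConnectome", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (nrow(m) < 2L) msg <- c(msg, "need at least 2 regions")
  tol <- 1e-8
  if (max(abs(m - t(m))) > tol) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(m) - 1) > tol)) msg <- c(msg, "diagonal must be 1")
  if (min(m) < -1 - tol || max(m) > 1 + tol)
    msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FunctionalConnectome from a correlation matrix
#'
#' @param matrix symmetric correlation matrix with unit diagonal.
#' @param subjectID subject identifier.
#' @param sessionLabel session label, default `"full"`.
#' @return A [FunctionalConnectome-class] object.
#' @export
functionalConnectome <- function(matrix, subjectID, sessionLabel = "full") {
  m <- as.matrix(matrix)
  new("FunctionalConnectome", subjectID = as.character(subjectID),
      sessionLabel = sessionLabel, matrix = m)
}

#' GroupEdgeMatrix: stacked test/retest edge vectors for a cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `"edges"`
#' assay is an E x 2N matrix: one row per connectome edge, one column per
#' (subject, session) pair — all N restA columns first (in subject order),
#' then the matched N restB columns. `colData` carries `subject` and
#' `session`.
#'
#' @seealso [buildGroupMatrix()], [decomposeGroup()], [sweepIdentifiability()]
#' @export
setClass("GroupEdgeMatrix", contains = "SummarizedExperiment")

setValidity("GroupEdgeMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  if (!all(c("subject", "session") %in% colnames(cd)))
    return("colData must contain 'subject' and 'session'")
  if (!all(cd$session %in% c("restA", "restB")))
    msg <- c(msg, "sessions must be restA or restB")
  tabA <- cd$subject[cd$session == "restA"]
  tabB <- cd$subject[cd$session == "restB"]
  if (anyDuplicated(tabA) || anyDuplicated(tabB) ||
      !setequal(tabA, tabB) || length(tabA) != length(tabB))
    msg <- c(msg, "exactly one restA and one restB column per subject required")
  if (length(msg)) msg else TRUE
})

#' PCABasis: group-level PCA decomposition of a GroupEdgeMatrix
#'
#' Stores the orthonormal edge-space loadings, the per-column scores, the
#' per-edge means removed before decomposition, and the explained-variance
#' ratios (descending, summing to 1 over retained components).
#'
#' @slot loadings E x k numeric matrix, orthonormal columns.
#' @slot scores k x 2N numeric matrix; column j holds the coordinates of
#'   connectome column j in the component basis.
#' @slot edgeMeans numeric length-E vector of per-edge means.
#' @slot explainedVarianceRatio numeric length-k, descending, sums to 1.
#' @slot colData data.frame with `subject` and `session` per column.
#' @seealso [decomposeGroup()], [reconstructAt()]
#' @export
setClass("PCABasis",
  slots = c(loadings = "matrix", scores = "matrix", edgeMeans = "numeric",
            explainedVarianceRatio = "numeric", colData = "data.frame")
)

setValidity("PCABasis", function(object) {
  msg <- character()
  k <- ncol(object@loadings)
  if (nrow(object@scores) != k) msg <- c(msg, "scores must have one row per component")
  if (length(object@edgeMeans) != nrow(object@loadings))
    msg <- c(msg, "edgeMeans length must equal number of edges")
  if (length(object@explainedVarianceRatio) != k)
    msg <- c(msg, "one explained-variance ratio per component required")
  evr <- object@explainedVarianceRatio
  if (k && is.unsorted(rev(evr), strictly = FALSE))
    msg <- c(msg, "explained-variance ratios must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' IdentifiabilityProfile: the reconstruction sweep result
#'
#' For each candidate number of principal components m, the profile records
#' the mean within-subject test/retest correlation (`iSelf`), the mean
#' between-subject correlation (`iOthers`), differential identifiability
#' `iDiff = 100 * (iSelf - iOthers)`, and the cumulative explained-variance
#' fraction. `mStar` is the smallest m maximizing `iDiff`.
#'
#' @slot mValues integer vector of PC counts swept.
#' @slot iSelf,iOthers numeric, same length, correlation scale.
#' @slot iDiff numeric, `100 * (iSelf - iOthers)`.
#' @slot cumR2 numeric cumulative explained-variance fraction at each m.
#' @slot mStar integer, smallest argmax of `iDiff`.
#' @seealso [sweepIdentifiability()], [identifiabilityScores()]
#' @export
setClass("IdentifiabilityProfile",
  slots = c(mValues = "integer", iSelf = "numeric", iOthers = "numeric",
            iDiff = "numeric", cumR2 = "numeric", mStar = "integer")
)

setValidity("IdentifiabilityProfile", function(object) {
  n <- length(object@mValues)
  if (any(lengths(list(object@iSelf, object@iOthers, object@iDiff,
                       object@cumR2)) != n))
    return("profile columns must have equal length")
  if (max(abs(object@iDiff - 100 * (object@iSelf - object@iOthers))) > 1e-8)
    return("iDiff must equal 100 * (iSelf - iOthers)")
  if (!(object@mStar %in% object@mValues))
    return("mStar must be one of the swept m values")
  TRUE
})

#' EdgeMask: signed edge selection for one outcome
#'
#' Two disjoint logical vectors over the canonical edge space: edges whose
#' correlation with the outcome exceeded the selection threshold (positive
#' mask) and edges below its negative (negative mask).
#'
#' @slot positive,negative logical vectors of length E, disjoint.
#' @slot threshold numeric selection threshold on |r|.
#' @slot outcome character, outcome-measure name.
#' @seealso [selectEdges()], [intersectMasks()], [maskStrengths()]
#' @export
setClass("EdgeMask",
  slots = c(positive = "logical", negative = "logical",
            threshold = "numeric", outcome = "character")
)

setValidity("EdgeMask", function(object) {
  msg <- character()
  if (length(object@positive) != length(object@negative))
    msg <- c(msg, "positive and negative masks must have equal length")
  else if (any(object@positive & object@negative))
    msg <- c(msg, "positive and negative masks must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct an EdgeMask
#'
#' @param positive,negative logical edge vectors (disjoint).
#' @param threshold selection threshold used.
#' @param outcome outcome name.
#' @return An [EdgeMask-class] object.
#' @export
edgeMask <- function(positive, negative, threshold = NA_real_,
                     outcome = NA_character_) {
  new("EdgeMask", positive = as.logical(positive),
      negative = as.logical(negative),
      threshold = as.numeric(threshold), outcome = as.character(outcome))
}

#' CPMModel: linear model from mask strengths to an outcome
#'
#' Ordinary-least-squares coefficients mapping the positive- and
#' negative-mask strengths of a connectome to a z-scored outcome. A mask side
#' that was empty at fit time has its coefficient recorded as `NA` and
#' contributes nothing to predictions.
#'
#' @slot mask the [EdgeMask-class] used.
#' @slot intercept numeric.
#' @slot betaPos,betaNeg numeric coefficients; `NA` = predictor dropped.
#' @slot sessionMode `"single"`, `"averaged"` or `"dual"`.
#' @seealso [fitCPM()], [predictCPM()], [dualSessionModel()]
#' @export
setClass("CPMModel",
  slots = c(mask = "EdgeMask", intercept = "numeric", betaPos = "numeric",
            betaNeg = "numeric", sessionMode = "character")
)

setValidity("CPMModel", function(object) {
  if (!is.finite(object@intercept)) return("intercept must be finite")
  if (!is.na(object@betaPos) && !is.finite(object@betaPos))
    return("betaPos must be finite or NA")
  if (!is.na(object@betaNeg) && !is.finite(object@betaNeg))
    return("betaNeg must be finite or NA")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic test/retest cohort generator
#'
#' @slot nSubjects,nRegions,nTimepoints integers; `nTimepoints` is used only
#'   by the time-series generator.
#' @slot nGroupComponents number of shared group-structure patterns.
#' @slot groupScale loading scale of the group patterns (correlation units).
#' @slot fingerprintScale standard deviation of the per-subject edge
#'   component, drawn once per subject and reused for both sessions.
#' @slot sessionNoiseScale standard deviation of independent per-session
#'   edge noise.
#' @slot plantedMasks list with logical `positive`/`negative` edge vectors
#'   per synthetic outcome (may be empty).
#' @slot effectSizes named list per outcome: `list(pos =, neg =)` scalars.
#' @slot outcomeNoiseScale standard deviation of outcome noise, in units of
#'   the noise-free outcome's standard deviation.
#' @slot seed integer master seed.
#' @seealso [syntheticConfig()], [generateFCCohort()]
#' @export
setClass("SyntheticConfig",
  slots = c(nSubjects = "integer", nRegions = "integer",
            nTimepoints = "integer", nGroupComponents = "integer",
            groupScale = "numeric", fingerprintScale = "numeric",
            sessionNoiseScale = "numeric", plantedMasks = "list",
            effectSizes = "list", outcomeNoiseScale = "numeric",
            seed = "integer")
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nRegions < 3L) msg <- c(msg, "nRegions must be >= 3")
  scales <- c(object@groupScale, object@fingerprintScale,
              object@sessionNoiseScale, object@outcomeNoiseScale)
  if (any(scales < 0)) msg <- c(msg, "all scales must be >= 0")
  for (pm in object@plantedMasks)
    if (any(pm$positive & pm$negative)) {
      msg <- c(msg, "planted positive/negative sets must be disjoint")
      break
    }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated paired test/retest cohort with ground truth
#'
#' @slot restA,restB E x N numeric matrices of edge vectors (one column per
#'   subject, matched order).
#' @slot subjectIDs character length N.
#' @slot parcellation the synthetic [Parcellation-class].
#' @slot outcomes data.frame with `subject` plus one column per synthetic
#'   outcome (empty when no masks were planted).
#' @slot groundTruth list: subject components, planted masks, true effect
#'   sizes, config.
#' @slot timeSeries list of per-subject session time series (time-series
#'   generator only; empty otherwise).
#' @seealso [generateFCCohort()], [generateTimeseriesCohort()]
#' @export
setClass("SyntheticCohort",
  slots = c(restA = "matrix", restB = "matrix", subjectIDs = "character",
            parcellation = "Parcellation", outcomes = "data.frame",
            groundTruth = "list", timeSeries = "list")
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!identical(dim(object@restA), dim(object@restB)))
    msg <- c(msg, "restA and restB must have identical dimensions")
  if (ncol(object@restA) != length(object@subjectIDs))
    msg <- c(msg, "one column per subject required")
  if (length(msg)) msg else TRUE
})
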