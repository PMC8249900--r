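#' Accessors for connfinger classes
#'
#' Small accessor generics: `subjectID()` and `sessionLabel()` work on time
#' series and connectomes; `edgeVector()` returns the canonical row-major
#' upper-triangle edge vector of a connectome; `tsValues()` the timepoint x
#' region matrix; `fcMatrix()` the full correlation matrix; `nRegions()` the
#' region count; `nSubjects()` the subject count of a group object.
#'
#' @param x an object of one of the package's classes.
#' @return The corresponding slot or derived value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))
#' @rdname accessors
#' @export
setGeneric("edgeVector", function(x) standardGeneric("edgeVector"))
#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))
#' @rdname accessors
#' @export
setGeneric("fcMatrix", function(x) standardGeneric("fcMatrix"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setMethod("subjectID", "RegionalTimeSeries", function(x) x@subjectID)
#' @rdname accessors
#' @export
setMethod("subjectID", "FunctionalConnectome", function(x) x@subjectID)
#' @rdname accessors
#' @export
setMethod("sessionLabel", "RegionalTimeSeries", function(x) x@sessionLabel)
#' @rdname accessors
#' @export
setMethod("sessionLabel", "FunctionalConnectome", function(x) x@sessionLabel)
#' @rdname accessors
#' @export
setMethod("tsValues", "RegionalTimeSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fcMatrix", "FunctionalConnectome", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("edgeVector", "FunctionalConnectome",
          function(x) vectorizeConnectome(x))
#' @rdname accessors
#' @export
setMethod("nRegions", "RegionalTimeSeries", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nRegions", "FunctionalConnectome", function(x) nrow(x@matrix))
#' @rdname accessors
#' @export
setMethod("nRegions", "Parcellation", function(x) length(x@regionIDs))
#' @rdname accessors
#' @export
setMethod("nSubjects", "GroupEdgeMatrix",
          function(x) ncol(x) %/% 2L)
#' @rdname accessors
#' @export
setMethod("nSubjects", "SyntheticCohort", function(x) ncol(x@restA))

#' Parcellation accessors
#'
#' @param x a [Parcellation-class].
#' @return `regionIDs()`: character vector; `rsnLabels()`: character vector;
#'   `regionCoordinates()`: R x 3 matrix (0-row when absent).
#' @name parcellation-accessors
NULL

#' @rdname parcellation-accessors
#' @export
setGeneric("regionIDs", function(x) standardGeneric("regionIDs"))
#' @rdname parcellation-accessors
#' @export
setGeneric("rsnLabels", function(x) standardGeneric("rsnLabels"))
#' @rdname parcellation-accessors
#' @export
setGeneric("regionCoordinates", function(x) standardGeneric("regionCoordinates"))
#' @rdname parcellation-accessors
#' @export
setMethod("regionIDs", "Parcellation", function(x) x@regionIDs)
#' @rdname parcellation-accessors
#' @export
setMethod("rsnLabels", "Parcellation", function(x) x@rsnLabels)
#' @rdname parcellation-accessors
#' @export
setMethod("regionCoordinates", "Parcellation", function(x) x@coordinates)

#' Extract one session's edge matrix from a GroupEdgeMatrix
#'
#' @param x a [GroupEdgeMatrix-class].
#' @param session `"restA"` or `"restB"`.
#' @return E x N numeric matrix, columns in subject order, named by subject.
#' @export
setGeneric("sessionMatrix", function(x, session) standardGeneric("sessionMatrix"))

#' @rdname sessionMatrix
#' @export
setMethod("sessionMatrix", "GroupEdgeMatrix", function(x, session) {
  session <- match.arg(session, c("restA", "restB"))
  cd <- SummarizedExperiment::colData(x)
  keep <- cd$session == session
  m <- SummarizedExperiment::assay(x, "edges")[, keep, drop = FALSE]
  colnames(m) <- cd$subject[keep]
  m
})

#' @rdname accessors
#' @export
setMethod("nSubjects", "PCABasis",
          function(x) nrow(x@colData) %/% 2L)

#' Optimal PC count of an identifiability profile
#'
#' @param x an [IdentifiabilityProfile-class].
#' @return Integer: the smallest number of PCs maximizing differential
#'   identifiability.
#' @export
setGeneric("mStar", function(x) standardGeneric("mStar"))
#' @rdname mStar
#' @export
setMethod("mStar", "IdentifiabilityProfile", function(x) x@mStar)

#' @describeIn IdentifiabilityProfile-class coerce the sweep to a data.frame
#'   with columns `m`, `iSelf`, `iOthers`, `iDiff`, `cumR2`.
#' @param x an IdentifiabilityProfile.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "IdentifiabilityProfile", function(x, ...) {
  data.frame(m = x@mValues, iSelf = x@iSelf, iOthers = x@iOthers,
             iDiff = x@iDiff, cumR2 = x@cumR2)
})

#' Mask accessors
#'
#' @param x an [EdgeMask-class].
#' @return `positiveEdges()`/`negativeEdges()`: logical vectors;
#'   `maskSize()`: total number of selected edges (both signs).
#' @name mask-accessors
NULL

#' @rdname mask-accessors
#' @export
setGeneric("positiveEdges", function(x) standardGeneric("positiveEdges"))
#' @rdname mask-accessors
#' @export
setGeneric("negativeEdges", function(x) standardGeneric("negativeEdges"))
#' @rdname mask-accessors
#' @export
setGeneric("maskSize", function(x) standardGeneric("maskSize"))
#' @rdname mask-accessors
#' @export
setMethod("positiveEdges", "EdgeMask", function(x) x@positive)
#' @rdname mask-accessors
#' @export
setMethod("negativeEdges", "EdgeMask", function(x) x@negative)
#' @rdname mask-accessors
#' @export
setMethod("maskSize", "EdgeMask", function(x) sum(x@positive) + sum(x@negative))

#' CPM model coefficients
#'
#' @param object a [CPMModel-class].
#' @param ... unused.
#' @return Named numeric vector `(intercept, betaPos, betaNeg)`; dropped
#'   predictors are `NA`.
#' @export
setMethod("coef", "CPMModel", function(object, ...) {
  c(intercept = object@intercept, betaPos = object@betaPos,
    betaNeg = object@betaNeg)
})

setMethod("show", "RegionalTimeSeries", function(object) {
  cat(sprintf("RegionalTimeSeries: subject %s, session %s\n",
              object@subjectID, object@sessionLabel))
  cat(sprintf("  %d timepoints x %d regions, TR = %gs, %d censored frames\n",
              nrow(object@values), ncol(object@values),
              object@repetitionTime, sum(object@censorMask)))
})

setMethod("show", "FunctionalConnectome", function(object) {
  R <- nrow(object@matrix)
  cat(sprintf("FunctionalConnectome: subject %s, session %s\n",
              object@subjectID, object@sessionLabel))
  cat(sprintf("  %d regions, %d edges\n", R, (R * (R - 1L)) %/% 2L))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d regions, %d RSNs%s\n",
              length(object@regionIDs), length(unique(object@rsnLabels)),
              if (nrow(object@coordinates)) ", with coordinates" else ""))
  print(table(factor(object@rsnLabels, levels = RSN_LEVELS)))
})

setMethod("show", "IdentifiabilityProfile", function(object) {
  i <- match(object@mStar, object@mValues)
  cat("IdentifiabilityProfile\n")
  cat(sprintf("  swept m = %d..%d (%d values)\n", min(object@mValues),
              max(object@mValues), length(object@mValues)))
  cat(sprintf("  optimum m* = %d: iSelf = %.4f, iOthers = %.4f, iDiff = %.2f, cumR2 = %.3f\n",
              object@mStar, object@iSelf[i], object@iOthers[i],
              object@iDiff[i], object@cumR2[i]))
})

setMethod("show", "EdgeMask", function(object) {
  cat(sprintf("EdgeMask (%s): %d positive, %d negative of %d edges (threshold %g)\n",
              object@outcome, sum(object@positive), sum(object@negative),
              length(object@positive), object@threshold))
})

setMethod("show", "CPMModel", function(object) {
  cat(sprintf("CPMModel (%s, %s-session)\n", object@mask@outcome,
              object@sessionMode))
  cat(sprintf("  intercept = %.4g, betaPos = %.4g (|mask| = %d), betaNeg = %.4g (|mask| = %d)\n",
              object@intercept, object@betaPos, sum(object@mask@positive),
              object@betaNeg, sum(object@mask@negative)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects, %d edges (%d regions), %d outcome(s)%s\n",
              ncol(object@restA), nrow(object@restA),
              length(object@parcellation@regionIDs),
              max(0L, ncol(object@outcomes) - 1L),
              if (length(object@timeSeries)) ", with time series" else ""))
})
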