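#' Z-score outcomes relative to a training cohort
#'
#' Standardizes every outcome column of `applyTo` using the mean and
#' standard deviation computed on the training table only, so validation
#' scores are expressed on the training cohort's scale.
#'
#' @param train data.frame with a `subject` column plus numeric outcome
#'   columns; defines the reference mean/SD per outcome.
#' @param applyTo data.frame with the same outcome columns; defaults to
#'   `train` (self-standardization).
#' @return `applyTo` with outcome columns replaced by
#'   `(x - trainMean) / trainSD`; the reference parameters are attached as
#'   attributes `center` and `scale`.
#' @export
zscoreOutcomes <- function(train, applyTo = train) {
  outcomeCols <- setdiff(names(train), "subject")
  mu <- vapply(train[outcomeCols], mean, numeric(1))
  sigma <- vapply(train[outcomeCols], sd, numeric(1))
  if (any(sigma == 0))
    stop("zero training SD for outcome(s): ",
         paste(outcomeCols[sigma == 0], collapse = ", "))
  out <- applyTo
  for (nm in outcomeCols) out[[nm]] <- (applyTo[[nm]] - mu[nm]) / sigma[nm]
  attr(out, "center") <- mu
  attr(out, "scale") <- sigma
  out
}

#' Select outcome-correlated edges into signed masks
#'
#' For each edge, the Pearson correlation between its values across subjects
#' and the outcome is computed. Edges with r strictly above `threshold` form
#' the positive mask; edges with r strictly below `-threshold` form the
#' negative mask. Edges with zero variance across subjects (correlation
#' undefined) are excluded from both.
#'
#' @param fcs connectome set (E x N matrix or list of
#'   [FunctionalConnectome-class]), N >= 3 subjects.
#' @param outcome numeric scores, one per subject, nonconstant.
#' @param threshold selection threshold on |r|, default 0.1.
#' @param outcomeName label stored in the mask.
#' @return An [EdgeMask-class].
#' @export
selectEdges <- function(fcs, outcome, threshold = 0.1,
                        outcomeName = NA_character_) {
  X <- .edgeMatrix(fcs)
  if (ncol(X) < 3L) stop("edge selection needs at least 3 subjects")
  if (length(outcome) != ncol(X))
    stop("one outcome value per subject required")
  if (sd(outcome) == 0) stop("outcome is constant; correlations undefined")
  r <- suppressWarnings(as.numeric(cor(t(X), outcome)))
  r[apply(X, 1, sd) == 0] <- NA_real_
  edgeMask(positive = !is.na(r) & r > threshold,
           negative = !is.na(r) & r < -threshold,
           threshold = threshold, outcome = outcomeName)
}

#' Intersect two signed edge masks
#'
#' Same-sign intersection: an edge survives only if selected with the same
#' sign in both masks (used to keep edges robust across the restA and restB
#' selections).
#'
#' @param mA,mB [EdgeMask-class] objects over the same edge space.
#' @return An [EdgeMask-class].
#' @export
intersectMasks <- function(mA, mB) {
  if (length(mA@positive) != length(mB@positive))
    stop("edge-space mismatch between masks")
  edgeMask(positive = mA@positive & mB@positive,
           negative = mA@negative & mB@negative,
           threshold = mA@threshold, outcome = mA@outcome)
}

#' Mask strengths: summed edge values within each mask side
#'
#' The strength of a connectome in a mask is the sum of its edge values over
#' the mask's edges; an empty mask side contributes strength 0.
#'
#' @param fcs a single connectome (object or edge vector) or a connectome
#'   set (E x N matrix / list).
#' @param mask an [EdgeMask-class].
#' @return data.frame with one row per connectome and columns `pos`, `neg`.
#' @export
maskStrengths <- function(fcs, mask) {
  X <- .edgeMatrix(fcs)
  if (nrow(X) != length(mask@positive))
    stop("edge-space mismatch between connectomes and mask")
  data.frame(
    pos = colSums(X[mask@positive, , drop = FALSE]),
    neg = colSums(X[mask@negative, , drop = FALSE]))
}

#' Fit a CPM linear model from mask strengths
#'
#' Ordinary least squares of the (z-scored) outcome on the positive- and
#' negative-mask strengths with an intercept. If one mask side is empty its
#' predictor is dropped and the coefficient recorded as `NA`; if both are
#' empty no model exists and an error is raised.
#'
#' @param fcs training connectome set.
#' @param outcome z-scored scores, one per subject (N >= 3).
#' @param mask an [EdgeMask-class].
#' @param sessionMode label stored on the model.
#' @return A [CPMModel-class].
#' @export
fitCPM <- function(fcs, outcome, mask, sessionMode = "single") {
  X <- .edgeMatrix(fcs)
  if (ncol(X) < 3L) stop("model fitting needs at least 3 subjects")
  s <- maskStrengths(X, mask)
  usePos <- any(mask@positive)
  useNeg <- any(mask@negative)
  if (!usePos && !useNeg) stop("both mask sides are empty; no predictors")
  D <- cbind(intercept = 1,
             if (usePos) cbind(pos = s$pos),
             if (useNeg) cbind(neg = s$neg))
  fit <- lm.fit(D, outcome)
  if (fit$rank < ncol(D)) {
    degc <- paste(colnames(D)[is.na(fit$coefficients)], collapse = ", ")
    stop("collinear or constant predictors (", degc,
         "); strengths carry no independent information")
  }
  cf <- fit$coefficients
  new("CPMModel", mask = mask,
      intercept = unname(cf["intercept"]),
      betaPos = if (usePos) unname(cf["pos"]) else NA_real_,
      betaNeg = if (useNeg) unname(cf["neg"]) else NA_real_,
      sessionMode = sessionMode)
}

#' Predict outcomes from connectomes with a CPM model
#'
#' `prediction = intercept + betaPos * sPos + betaNeg * sNeg`; a predictor
#' dropped at fit time contributes 0.
#'
#' @param model a [CPMModel-class].
#' @param fcs connectome set (or single connectome) in the model's edge
#'   space.
#' @return Numeric vector of predicted (z-scored) outcomes.
#' @export
predictCPM <- function(model, fcs) {
  s <- maskStrengths(fcs, model@mask)
  bp <- if (is.na(model@betaPos)) 0 else model@betaPos
  bn <- if (is.na(model@betaNeg)) 0 else model@betaNeg
  model@intercept + bp * s$pos + bn * s$neg
}

#' Dual-session CPM model for optimally reconstructed connectomes
#'
#' The denoised test/retest variant: edges are selected separately on the
#' restA and restB sets and intersected (same sign), one model is fit per
#' session with that common mask, and the coefficients of the two models are
#' averaged elementwise.
#'
#' @param fcsA,fcsB paired restA/restB connectome sets (same subjects, same
#'   order).
#' @param outcome z-scored scores, one per subject.
#' @param threshold edge-selection threshold, default 0.1.
#' @param outcomeName label stored on the mask.
#' @return A [CPMModel-class] with `sessionMode = "dual"`.
#' @seealso [dualSessionPredict()]
#' @export
dualSessionModel <- function(fcsA, fcsB, outcome, threshold = 0.1,
                             outcomeName = NA_character_) {
  A <- .edgeMatrix(fcsA)
  B <- .edgeMatrix(fcsB)
  stopifnot(identical(dim(A), dim(B)))
  mask <- intersectMasks(
    selectEdges(A, outcome, threshold, outcomeName),
    selectEdges(B, outcome, threshold, outcomeName))
  if (!any(mask@positive) && !any(mask@negative))
    stop("intersect mask is empty for outcome ", outcomeName)
  fitA <- fitCPM(A, outcome, mask, sessionMode = "dual")
  fitB <- fitCPM(B, outcome, mask, sessionMode = "dual")
  avg <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else (a + b) / 2
  new("CPMModel", mask = mask,
      intercept = (fitA@intercept + fitB@intercept) / 2,
      betaPos = avg(fitA@betaPos, fitB@betaPos),
      betaNeg = avg(fitA@betaNeg, fitB@betaNeg),
      sessionMode = "dual")
}

#' Session-averaged prediction for dual-session models
#'
#' Applies the model separately to each validation subject's restA and restB
#' connectomes and averages the two predictions.
#'
#' @param model a [CPMModel-class].
#' @param fcsA,fcsB paired restA/restB connectome sets for the validation
#'   subjects (same subjects, same order).
#' @return Numeric vector of averaged predictions.
#' @export
dualSessionPredict <- function(model, fcsA, fcsB) {
  A <- .edgeMatrix(fcsA)
  B <- .edgeMatrix(fcsB)
  if (!identical(dim(A), dim(B)))
    stop("unpaired validation subjects: restA and restB sets differ")
  (predictCPM(model, A) + predictCPM(model, B)) / 2
}

#' Serialize / deserialize a CPM model as flat text
#'
#' Writes outcome name, threshold, session mode, coefficients and the edge
#' ids of each mask side in a simple `key<TAB>value` format.
#'
#' @param model a [CPMModel-class].
#' @param path file path.
#' @return `writeCPMModel()` the model invisibly; `readCPMModel()` the
#'   rebuilt [CPMModel-class] (requires `nEdges`, the edge-space size).
#' @export
writeCPMModel <- function(model, path) {
  lines <- c(
    paste0("outcome\t", model@mask@outcome),
    paste0("threshold\t", format(model@mask@threshold, digits = 17)),
    paste0("session_mode\t", model@sessionMode),
    paste0("intercept\t", format(model@intercept, digits = 17)),
    paste0("beta_pos\t", format(model@betaPos, digits = 17)),
    paste0("beta_neg\t", format(model@betaNeg, digits = 17)),
    paste0("n_edges\t", length(model@mask@positive)),
    paste0("positive_edges\t", paste(which(model@mask@positive), collapse = ",")),
    paste0("negative_edges\t", paste(which(model@mask@negative), collapse = ",")))
  writeLines(lines, path)
  invisible(model)
}

#' @rdname writeCPMModel
#' @export
readCPMModel <- function(path) {
  kv <- read.delim(path, header = FALSE, col.names = c("key", "value"),
                   colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  E <- as.integer(get("n_edges"))
  parseIdx <- function(s) {
    s <- if (is.na(s)) "" else s
    v <- logical(E)
    if (nzchar(s)) v[as.integer(strsplit(s, ",")[[1]])] <- TRUE
    v
  }
  mask <- edgeMask(parseIdx(get("positive_edges")),
                   parseIdx(get("negative_edges")),
                   threshold = as.numeric(get("threshold")),
                   outcome = get("outcome"))
  new("CPMModel", mask = mask,
      intercept = as.numeric(get("intercept")),
      betaPos = as.numeric(get("beta_pos")),
      betaNeg = as.numeric(get("beta_neg")),
      sessionMode = get("session_mode"))
}
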