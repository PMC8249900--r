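#' Build a split-half cross-validation plan
#'
#' Draws `nReps` independent random partitions of the cohort into a training
#' and a validation half (the training half receives the extra subject when
#' the cohort size is odd). Each repetition's split is drawn under its own
#' child seed derived from the master seed by a counter scheme, so
#' repetitions are reproducible individually.
#'
#' @param subjectIDs character vector of at least 6 subjects.
#' @param nReps number of repetitions, default 1000.
#' @param seed integer master seed.
#' @return An object of class `CVPlan`: list with `subjectIDs`, `nReps`,
#'   `seed` and `splits` (per repetition: `train`, `validation`).
#' @export
makeCVPlan <- function(subjectIDs, nReps = 1000, seed = 1) {
  subjectIDs <- as.character(subjectIDs)
  n <- length(subjectIDs)
  if (n < 6L)
    stop("need at least 6 subjects to fit models on both halves, got ", n)
  nTrain <- ceiling(n / 2)
  splits <- lapply(seq_len(nReps), function(k) {
    idx <- .withSeed(.childSeed(seed, k), sample.int(n, nTrain))
    list(train = subjectIDs[sort(idx)],
         validation = subjectIDs[sort(setdiff(seq_len(n), idx))])
  })
  structure(list(subjectIDs = subjectIDs, nReps = as.integer(nReps),
                 seed = as.integer(seed), splits = splits),
            class = "CVPlan")
}

#' @export
print.CVPlan <- function(x, ...) {
  cat(sprintf("CVPlan: %d subjects, %d repetitions (seed %d), %d/%d split\n",
              length(x$subjectIDs), x$nReps, x$seed,
              length(x$splits[[1]]$train), length(x$splits[[1]]$validation)))
  invisible(x)
}

#' Frobenius divergence between two edgewise correlation vectors
#'
#' Euclidean norm of the difference between the restA and restB edge-outcome
#' correlation vectors; values near zero denote stable correlation structure
#' across sessions.
#'
#' @param corrA,corrB numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
frobeniusDivergence <- function(corrA, corrB) {
  if (length(corrA) != length(corrB))
    stop("correlation vectors have different lengths")
  sqrt(sum((corrA - corrB)^2))
}

#' Same-sign mask overlap
#'
#' Number of edges selected with the same sign in both masks divided by the
#' number of edges selected (either sign) in either mask. Undefined (NA)
#' when both masks are empty.
#'
#' @param mA,mB [EdgeMask-class] objects over the same edge space.
#' @return Scalar in \[0, 1\], or `NA` when both masks are empty.
#' @export
maskOverlap <- function(mA, mB) {
  if (length(mA@positive) != length(mB@positive))
    stop("edge-space mismatch between masks")
  inter <- sum((mA@positive & mB@positive) | (mA@negative & mB@negative))
  uni <- sum(mA@positive | mA@negative | mB@positive | mB@negative)
  if (uni == 0L) NA_real_ else inter / uni
}

#' Specificity of edge selection across outcome measures
#'
#' Averages the pairwise Frobenius divergence of edge-outcome correlation
#' vectors and the pairwise same-sign mask overlap over all unordered pairs
#' of outcome measures (computed on one session only, typically restA). Low
#' overlap across outcomes relative to the restA/restB stability overlap
#' indicates that different outcomes select genuinely different edges.
#'
#' @param corrVectors named list (one per outcome) of edgewise correlation
#'   vectors, or `NULL`.
#' @param masks named list (one per outcome) of [EdgeMask-class], or `NULL`.
#' @return List with `frobenius` and `overlap` (mean over outcome pairs;
#'   `NA` where the corresponding input list was `NULL`).
#' @export
specificityProfile <- function(corrVectors = NULL, masks = NULL) {
  K <- max(length(corrVectors), length(masks))
  if (K < 2L) stop("specificity requires at least 2 outcome measures")
  pairs <- combn(K, 2)
  frob <- if (is.null(corrVectors)) NA_real_ else
    mean(apply(pairs, 2, function(p)
      frobeniusDivergence(corrVectors[[p[1]]], corrVectors[[p[2]]])))
  ov <- if (is.null(masks)) NA_real_ else
    mean(apply(pairs, 2, function(p)
      maskOverlap(masks[[p[1]]], masks[[p[2]]])), na.rm = TRUE)
  list(frobenius = frob, overlap = ov)
}

#' Paired permutation test with max-statistic family-wise correction
#'
#' Tests, per outcome, whether the paired differences (e.g. optimal-pipeline
#' minus original-pipeline validation correlation at each repetition) are
#' centered above zero. The statistic is the paired t (mean difference over
#' its standard error; a plain mean-difference statistic is available). The
#' null is built by flipping the sign of each repetition's difference row
#' (the same flips across all outcomes, preserving their dependence), and
#' each outcome's statistic is compared against the permutation distribution
#' of the maximum statistic across outcomes, which controls the family-wise
#' error rate. The observed arrangement is counted in the null, so p >=
#' 1/nPerm.
#'
#' @param diffs numeric matrix, repetitions x outcomes (a vector is treated
#'   as one outcome), at least 2 repetitions.
#' @param nPerm number of sign-flip draws, default 1000 (the identity flip
#'   replaces the first draw).
#' @param alpha significance level, default 0.01.
#' @param side `"greater"` (directional, default) or `"two.sided"`.
#' @param statistic `"t"` (default) or `"mean"`.
#' @param exact if `TRUE`, enumerate all 2^n sign patterns instead of
#'   sampling (n <= 20).
#' @param seed integer seed for the random flips.
#' @return data.frame with one row per outcome: `outcome`, `observed`,
#'   `p`, `significant` (`p <= alpha`); attributes `nPerm`, `alpha`,
#'   `side`, `correction = "tmax"`.
#' @export
pairedPermutationTmax <- function(diffs, nPerm = 1000, alpha = 0.01,
                                  side = c("greater", "two.sided"),
                                  statistic = c("t", "mean"),
                                  exact = FALSE, seed = 1) {
  side <- match.arg(side)
  statistic <- match.arg(statistic)
  D <- as.matrix(diffs)
  n <- nrow(D)
  K <- ncol(D)
  if (n < 2L) stop("need at least 2 repetitions")
  if (is.null(colnames(D))) colnames(D) <- paste0("outcome", seq_len(K))

  tstat <- function(M, ss) {                 # M: flips%*%D/n, per column
    if (statistic == "mean") return(M)
    v <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
    v[v < 0] <- 0
    out <- M / sqrt(v / n)
    out[v == 0] <- ifelse(M[v == 0] == 0, 0, sign(M[v == 0]) * Inf)
    out
  }
  ss <- colSums(D^2)
  obs <- tstat(matrix(colMeans(D), 1), ss)[1, ]

  if (exact) {
    if (n > 20L) stop("exact enumeration limited to 20 repetitions")
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    flips <- .withSeed(seed,
      matrix(sample(c(1, -1), nPerm * n, replace = TRUE), nPerm, n))
    flips[1, ] <- 1                          # observed arrangement included
  }
  permStat <- tstat(flips %*% D / n, ss)
  if (side == "two.sided") {
    permStat <- abs(permStat)
    obs <- abs(obs)
  }
  nullMax <- apply(permStat, 1, max)
  p <- vapply(obs, function(o) mean(nullMax >= o), numeric(1))
  res <- data.frame(outcome = colnames(D), observed = unname(obs),
                    p = unname(p), significant = unname(p <= alpha))
  attr(res, "nPerm") <- nrow(flips)
  attr(res, "alpha") <- alpha
  attr(res, "side") <- side
  attr(res, "correction") <- "tmax"
  res
}

# edgewise Pearson correlation of each edge with the outcome
.edgeOutcomeCor <- function(X, y) {
  r <- suppressWarnings(as.numeric(cor(t(X), y)))
  r
}

#' Run the full split-half cross-validation harness
#'
#' For each repetition of the plan: (1) the identifiability sweep is run
#' separately on the training and validation cohorts (they never share
#' data); (2) outcomes are z-scored with training-cohort parameters; (3) two
#' pipelines are evaluated per outcome — the "original" pipeline (full-rank
#' connectomes, edge selection and model fit on the restA/restB-averaged
#' connectome, applied to the averaged validation connectomes) and the
#' "optimal" pipeline (connectomes reconstructed at each cohort's own
#' optimum, dual-session model with intersected masks and
#' coefficient/prediction averaging); (4) stability (Frobenius divergence of
#' restA vs restB edge-outcome correlations, same-sign mask overlap),
#' test/retest generalization (model fit on restA evaluated on restA and on
#' restB of the training cohort) and validation performance (Pearson r of
#' predicted vs observed) are recorded. Repetition-level failures (e.g.
#' empty masks) are flagged per row, never silently dropped.
#'
#' @param cohort a [SyntheticCohort-class], or a list with elements `restA`,
#'   `restB` (E x N matrices) and `subjectIDs`.
#' @param plan a `CVPlan` from [makeCVPlan()].
#' @param outcomes data.frame (`subject` + outcome columns); defaults to the
#'   cohort's own outcome table.
#' @param threshold edge-selection threshold, default 0.1.
#' @param mRange PC sweep range passed to [sweepIdentifiability()] (default:
#'   full per-cohort range).
#' @return List with `results` (one row per repetition x outcome x mode),
#'   `specificity` (one row per repetition x mode), `summary` (means over
#'   successful repetitions by outcome x mode), `masks` (per mode/outcome:
#'   list of the per-repetition model masks, for consensus building) and
#'   `plan`.
#' @export
runSplitHalfCV <- function(cohort, plan, outcomes = NULL, threshold = 0.1,
                           mRange = NULL) {
  if (is(cohort, "SyntheticCohort")) {
    A <- cohort@restA; B <- cohort@restB; ids <- cohort@subjectIDs
    if (is.null(outcomes)) outcomes <- cohort@outcomes
  } else {
    A <- cohort$restA; B <- cohort$restB; ids <- as.character(cohort$subjectIDs)
  }
  if (is.null(outcomes) || ncol(outcomes) < 2L)
    stop("an outcome table with at least one outcome column is required")
  stopifnot(setequal(outcomes$subject, ids))
  outcomeNames <- setdiff(names(outcomes), "subject")
  modes <- c("original", "optimal")
  rows <- vector("list", plan$nReps * length(outcomeNames) * 2L)
  specRows <- vector("list", plan$nReps * 2L)
  masks <- setNames(lapply(modes, function(m)
    setNames(lapply(outcomeNames, function(o) vector("list", plan$nReps)),
             outcomeNames)), modes)
  ri <- 0L; si <- 0L

  for (k in seq_len(plan$nReps)) {
    sp <- plan$splits[[k]]
    iT <- match(sp$train, ids); iV <- match(sp$validation, ids)
    swT <- sweepIdentifiability(buildGroupMatrix(A[, iT, drop = FALSE],
                                                 B[, iT, drop = FALSE],
                                                 subjectIDs = sp$train), mRange)
    swV <- sweepIdentifiability(buildGroupMatrix(A[, iV, drop = FALSE],
                                                 B[, iV, drop = FALSE],
                                                 subjectIDs = sp$validation), mRange)
    sess <- list(
      original = list(AT = A[, iT, drop = FALSE], BT = B[, iT, drop = FALSE],
                      AV = A[, iV, drop = FALSE], BV = B[, iV, drop = FALSE]),
      optimal = list(AT = sessionMatrix(swT$optimal, "restA"),
                     BT = sessionMatrix(swT$optimal, "restB"),
                     AV = sessionMatrix(swV$optimal, "restA"),
                     BV = sessionMatrix(swV$optimal, "restB")))
    oT <- outcomes[match(sp$train, outcomes$subject), , drop = FALSE]
    oV <- outcomes[match(sp$validation, outcomes$subject), , drop = FALSE]
    zT <- zscoreOutcomes(oT)
    zV <- zscoreOutcomes(oT, oV)

    for (mode in modes) {
      S <- sess[[mode]]
      specCorr <- list(); specMasks <- list()
      for (nm in outcomeNames) {
        ri <- ri + 1L
        yT <- zT[[nm]]; yV <- zV[[nm]]
        row <- tryCatch({
          corrA <- .edgeOutcomeCor(S$AT, yT)
          corrB <- .edgeOutcomeCor(S$BT, yT)
          mkA <- selectEdges(S$AT, yT, threshold, nm)
          mkB <- selectEdges(S$BT, yT, threshold, nm)
          specCorr[[nm]] <- corrA
          specMasks[[nm]] <- mkA
          frob <- frobeniusDivergence(corrA, corrB)
          ovl <- maskOverlap(mkA, mkB)
          modelA <- fitCPM(S$AT, yT, mkA)
          rTrainA <- cor(predictCPM(modelA, S$AT), yT)
          rTrainB <- cor(predictCPM(modelA, S$BT), yT)
          if (mode == "original") {
            avgT <- (S$AT + S$BT) / 2
            avgV <- (S$AV + S$BV) / 2
            mk <- selectEdges(avgT, yT, threshold, nm)
            model <- fitCPM(avgT, yT, mk, sessionMode = "averaged")
            rVal <- cor(predictCPM(model, avgV), yV)
          } else {
            model <- dualSessionModel(S$AT, S$BT, yT, threshold, nm)
            mk <- model@mask
            rVal <- cor(dualSessionPredict(model, S$AV, S$BV), yV)
          }
          masks[[mode]][[nm]][[k]] <- mk
          data.frame(repetition = k, outcome = nm, mode = mode,
                     mStarTrain = mStar(swT$profile),
                     mStarValidation = mStar(swV$profile),
                     nPos = sum(mk@positive), nNeg = sum(mk@negative),
                     frobenius = frob, overlap = ovl,
                     rTrainA = rTrainA, rTrainB = rTrainB, rVal = rVal,
                     ok = TRUE, message = "", stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(repetition = k, outcome = nm, mode = mode,
                     mStarTrain = mStar(swT$profile),
                     mStarValidation = mStar(swV$profile),
                     nPos = NA_integer_, nNeg = NA_integer_,
                     frobenius = NA_real_, overlap = NA_real_,
                     rTrainA = NA_real_, rTrainB = NA_real_, rVal = NA_real_,
                     ok = FALSE, message = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
        rows[[ri]] <- row
      }
      si <- si + 1L
      specRows[[si]] <- if (length(specCorr) >= 2L) {
        sp2 <- specificityProfile(specCorr, specMasks)
        data.frame(repetition = k, mode = mode,
                   specFrobenius = sp2$frobenius, specOverlap = sp2$overlap)
      } else {
        data.frame(repetition = k, mode = mode,
                   specFrobenius = NA_real_, specOverlap = NA_real_)
      }
    }
  }
  results <- do.call(rbind, rows)
  specificity <- do.call(rbind, specRows)
  okRes <- results[results$ok, ]
  summary <- do.call(rbind, lapply(split(okRes,
      list(okRes$outcome, okRes$mode), drop = TRUE), function(d) {
    data.frame(outcome = d$outcome[1], mode = d$mode[1], nOK = nrow(d),
               mStarTrain = mean(d$mStarTrain),
               frobenius = mean(d$frobenius), overlap = mean(d$overlap, na.rm = TRUE),
               rTrainA = mean(d$rTrainA), rTrainB = mean(d$rTrainB),
               rVal = mean(d$rVal))
  }))
  rownames(summary) <- NULL
  list(results = results, specificity = specificity, summary = summary,
       masks = masks, plan = plan)
}
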