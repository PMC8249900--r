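#' Split a regional time series into surrogate test/retest halves
#'
#' Two splitting schemes are supported. `"half"` cuts the frame axis in two
#' contiguous blocks (the first block receives the extra frame when T is
#' odd), mimicking a test/retest pair taken from the first and second half of
#' one acquisition. `"interleaved"` sends even-position frames (1st, 3rd, ...)
#' to the first output and odd-position frames to the second, which doubles
#' the effective sampling interval of each output; both outputs therefore
#' carry twice the input repetition time. The censor mask, when present, is
#' split identically.
#'
#' @param ts a [RegionalTimeSeries-class] with at least 4 frames.
#' @param mode `"half"` or `"interleaved"`.
#' @return List of two [RegionalTimeSeries-class] objects labeled
#'   `"half1"`/`"half2"` (use [assignSessionLabels()] to randomize which is
#'   restA).
#' @examples
#' ts <- regionalTimeSeries(matrix(rnorm(20), 5, 4), "s1")
#' halves <- splitTimeSeries(ts, "half")
#' nrow(tsValues(halves[[1]]))  # 3 of 5 frames
#' @export
splitTimeSeries <- function(ts, mode = c("half", "interleaved")) {
  mode <- match.arg(mode)
  stopifnot(is(ts, "RegionalTimeSeries"))
  T <- nrow(ts@values)
  if (T < 4L)
    stop("degenerate input: need at least 4 timepoints to split, got ", T)
  idx1 <- switch(mode,
    half = seq_len(ceiling(T / 2)),
    interleaved = seq(1L, T, by = 2L))
  idx2 <- setdiff(seq_len(T), idx1)
  tr <- if (mode == "interleaved") 2 * ts@repetitionTime else ts@repetitionTime
  mk <- function(idx, lab) {
    regionalTimeSeries(ts@values[idx, , drop = FALSE], ts@subjectID,
      sessionLabel = lab, repetitionTime = tr,
      censorMask = if (length(ts@censorMask)) ts@censorMask[idx] else NULL)
  }
  list(mk(idx1, "half1"), mk(idx2, "half2"))
}

# deterministic per-subject stream: combine the master seed with a small
# hash of the subject id so the same seed reproduces every subject's flip
.subjectSeed <- function(seed, subjectID) {
  h <- sum(utf8ToInt(as.character(subjectID)) *
             seq_along(utf8ToInt(as.character(subjectID))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Randomly assign restA/restB labels to a pair of split halves
#'
#' The two halves of one subject's scan are assigned to "restA" and "restB"
#' by a seeded per-subject coin flip, avoiding any systematic bias toward the
#' first versus second half of the acquisition. The flip is deterministic
#' given the seed and the subject id, so labeling is reproducible subject by
#' subject and differs across subjects for a fixed seed.
#'
#' @param half1,half2 the two [RegionalTimeSeries-class] halves of one
#'   subject (same `subjectID`).
#' @param seed integer master seed.
#' @return List of the two series relabeled `"restA"` and `"restB"`, in that
#'   order.
#' @export
assignSessionLabels <- function(half1, half2, seed) {
  stopifnot(is(half1, "RegionalTimeSeries"), is(half2, "RegionalTimeSeries"))
  if (!identical(half1@subjectID, half2@subjectID))
    stop("halves belong to different subjects: ", half1@subjectID, " vs ",
         half2@subjectID)
  flip <- .withSeed(.subjectSeed(seed, half1@subjectID), runif(1) < 0.5)
  pair <- if (flip) list(half2, half1) else list(half1, half2)
  pair[[1]]@sessionLabel <- "restA"
  pair[[2]]@sessionLabel <- "restB"
  validObject(pair[[1]]); validObject(pair[[2]])
  pair
}

#' Exclude subjects with excessive frame censoring
#'
#' Subjects whose censored-frame fraction strictly exceeds `maxFraction`
#' (default 0.30, i.e. over 30% of frames flagged) are removed from the
#' cohort. A series without a censor mask counts as having zero censored
#' frames.
#'
#' @param cohort list of [RegionalTimeSeries-class] objects.
#' @param maxFraction maximum tolerated censored fraction (exclusive bound).
#' @return List with `kept` (the retained series) and `excluded`, a
#'   data.frame of `subject`, `fraction` for each removed series.
#' @export
applyCensorFilter <- function(cohort, maxFraction = 0.30) {
  frac <- vapply(cohort, function(ts) {
    if (!length(ts@censorMask)) 0 else mean(ts@censorMask)
  }, numeric(1))
  drop <- frac > maxFraction
  list(
    kept = cohort[!drop],
    excluded = data.frame(
      subject = vapply(cohort[drop], slot, character(1), "subjectID"),
      fraction = frac[drop])
  )
}

#' Compute a functional connectome from a regional time series
#'
#' Censored frames are deleted, then the pairwise Pearson correlation between
#' every pair of regional signals is computed over the remaining frames,
#' giving a symmetric correlation matrix with unit diagonal.
#'
#' @param ts a [RegionalTimeSeries-class]; after censoring at least 3 frames
#'   must remain and every region must have nonzero temporal variance.
#' @return A [FunctionalConnectome-class].
#' @examples
#' set.seed(1)
#' fc <- computeConnectome(regionalTimeSeries(matrix(rnorm(60), 20, 3), "s1"))
#' fcMatrix(fc)
#' @export
computeConnectome <- function(ts) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  v <- ts@values
  if (length(ts@censorMask)) v <- v[!ts@censorMask, , drop = FALSE]
  if (nrow(v) < 3L)
    stop("fewer than 3 usable frames after censoring (", nrow(v), ")")
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  m <- cor(v)
  diag(m) <- 1
  functionalConnectome(m, ts@subjectID, ts@sessionLabel)
}
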