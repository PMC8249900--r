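#' Read and write the plain-text interchange formats
#'
#' All on-disk formats are tab-separated text. Time series: T rows x R
#' columns with a header row of region ids; an optional companion censor
#' file holds one 0/1 per frame (1 = censored). Connectomes: square numeric
#' matrix with region ids as header row and first column. Edge vectors: two
#' columns, `edge` keyed as `"regionI__regionJ"` and `value`. Parcellation:
#' columns `region_id`, `rsn_label` and optional `x`, `y`, `z` (mm).
#' Outcomes: `subject` plus one numeric column per outcome measure.
#'
#' @param path file path.
#' @param subjectID,sessionLabel,repetitionTime metadata for the series.
#' @param censorPath optional path of the 0/1 censor file.
#' @name text-io
#' @return `readTimeSeries()`: a [RegionalTimeSeries-class];
#'   `readConnectome()`: a [FunctionalConnectome-class]; `readParcellation()`:
#'   a [Parcellation-class]; `readOutcomeTable()`: a data.frame; the writers
#'   return their input invisibly.
NULL

#' @rdname text-io
#' @export
readTimeSeries <- function(path, subjectID, sessionLabel = "full",
                           repetitionTime = 3, censorPath = NULL) {
  v <- as.matrix(read.delim(path, check.names = FALSE))
  cm <- if (!is.null(censorPath))
    as.logical(scan(censorPath, what = integer(), quiet = TRUE))
  regionalTimeSeries(v, subjectID, sessionLabel, repetitionTime, cm)
}

#' @rdname text-io
#' @param ts a [RegionalTimeSeries-class] to write.
#' @export
writeTimeSeries <- function(ts, path, censorPath = NULL) {
  write.table(ts@values, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(censorPath) && length(ts@censorMask))
    writeLines(as.character(as.integer(ts@censorMask)), censorPath)
  invisible(ts)
}

#' @rdname text-io
#' @export
readConnectome <- function(path, subjectID, sessionLabel = "full") {
  d <- read.delim(path, check.names = FALSE, row.names = 1L)
  functionalConnectome(as.matrix(d), subjectID, sessionLabel)
}

#' @rdname text-io
#' @param fc a [FunctionalConnectome-class] to write.
#' @param regionIDs optional region ids for the header (defaults to
#'   `R001...`).
#' @export
writeConnectome <- function(fc, path, regionIDs = NULL) {
  m <- fcMatrix(fc)
  ids <- regionIDs %||% colnames(m) %||% sprintf("R%03d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, ids)
  write.table(cbind(region = ids, as.data.frame(m)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(fc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname text-io
#' @param vec edge vector to write.
#' @param parc the [Parcellation-class] providing region ids for edge keys.
#' @export
writeEdgeVector <- function(vec, parc, path) {
  ei <- edgeIndex(parc)
  write.table(
    data.frame(edge = paste(ei$regionI, ei$regionJ, sep = "__"), value = vec),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vec)
}

#' @rdname text-io
#' @export
readEdgeVector <- function(path) {
  d <- read.delim(path)
  setNames(d$value, d$edge)
}

#' @rdname text-io
#' @export
readParcellation <- function(path) {
  d <- read.delim(path)
  coords <- if (all(c("x", "y", "z") %in% names(d)))
    as.matrix(d[, c("x", "y", "z")])
  parcellation(d$region_id, d$rsn_label, coords)
}

#' @rdname text-io
#' @param parc a [Parcellation-class] to write.
#' @export
writeParcellation <- function(parc, path) {
  d <- data.frame(region_id = parc@regionIDs, rsn_label = parc@rsnLabels)
  if (nrow(parc@coordinates)) {
    d$x <- parc@coordinates[, 1]; d$y <- parc@coordinates[, 2]
    d$z <- parc@coordinates[, 3]
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(parc)
}

#' @rdname text-io
#' @export
readOutcomeTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"subject" %in% names(d)) stop("outcome table needs a 'subject' column")
  d$subject <- as.character(d$subject)
  d
}

#' @rdname text-io
#' @param outcomes outcome data.frame to write.
#' @export
writeOutcomeTable <- function(outcomes, path) {
  write.table(outcomes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outcomes)
}
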