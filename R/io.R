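## Plain-text readers and writers: NN-interval files (one interval in ms
## per line), signal CSVs, session CSVs and feature-matrix CSVs. Readers
## reject malformed input with actionable messages; nothing is silently
## coerced.

#' Read an NN-interval text file
#'
#' One positive interval in milliseconds per line; blank lines and lines
#' starting with \code{#} are ignored. Beat times are reconstructed by
#' cumulative sum from time 0.
#'
#' @param path file path.
#' @return a \linkS4class{BeatSeries}.
#' @export
readNNFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- suppressWarnings(as.numeric(lines[keep]))
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: '%s' is not a positive number",
                 path, keep[bad[1]], lines[keep[bad[1]]]))
  BeatSeries(c(0, cumsum(vals) / 1000))
}

#' Write an NN-interval text file
#'
#' Canonical format: one interval in ms per line, four decimal places.
#' \code{readNNFile} followed by \code{writeNNFile} reproduces a canonical
#' file byte-for-byte.
#'
#' @param nn numeric NN intervals in ms, or a \linkS4class{BeatSeries}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNNFile <- function(nn, path) {
  if (is(nn, "BeatSeries")) nn <- nnIntervals(nn)
  if (any(!is.finite(nn) | nn <= 0)) stop("intervals must be positive")
  writeLines(sprintf("%.4f", nn), path)
  invisible(path)
}

#' Read a signal CSV
#'
#' Either two columns \code{time_s, amplitude} (the sampling rate is
#' inferred from the median time step and checked for regularity) or a
#' single \code{amplitude} column with \code{fs} supplied.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (required for single-column files).
#' @param modality \code{"ecg"} or \code{"pulse"}.
#' @return a \linkS4class{RawSignal}.
#' @export
readSignalCSV <- function(path, fs = NULL, modality = "pulse") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (ncol(df) >= 2L) {
    dt <- diff(df[[1]])
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9)
      stop("time column is not evenly sampled")
    RawSignal(df[[2]], 1 / stats::median(dt), modality = modality,
              startTime = df[[1]][1])
  } else {
    if (is.null(fs)) stop("single-column signal CSV requires fs")
    RawSignal(df[[1]], fs, modality = modality)
  }
}

#' Read a session CSV (question schedule and labels)
#'
#' Required columns: \code{question_id}, \code{start_s}, \code{end_s},
#' \code{label} (\code{"truth"} or \code{"lie"}). Overlapping spans and
#' unknown labels are errors. Labels are mapped to the binary convention
#' y = 1 truth, y = 0 lie.
#'
#' @param path file path.
#' @return data.frame with the original columns plus \code{y}.
#' @export
readSessionCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("question_id", "start_s", "end_s", "label")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("session CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$label %in% c("truth", "lie"))
  if (length(bad))
    stop(sprintf("unknown label '%s' in row %d (expected 'truth' or 'lie')",
                 df$label[bad[1]], bad[1]))
  if (any(df$end_s <= df$start_s)) stop("question spans must have end_s > start_s")
  o <- order(df$start_s)
  if (any(df$start_s[o][-1] < df$end_s[o][-nrow(df)]))
    stop("question spans overlap")
  df$y <- ifelse(df$label == "truth", 1, 0)
  df
}

#' Write a feature matrix CSV
#'
#' One row per window: \code{window_start_s}, \code{window_end_s}, then the
#' feature columns in canonical order (plus \code{y} and
#' \code{question_id} when labels are present).
#'
#' @param m an \linkS4class{HRVWindowMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(m, path) {
  stopifnot(is(m, "HRVWindowMatrix"))
  df <- data.frame(window_start_s = windowStarts(m),
                   window_end_s = windowEnds(m))
  y <- windowLabels(m)
  if (any(!is.na(y))) {
    df$y <- y
    df$question_id <- SummarizedExperiment::colData(m)$questionId
  }
  df <- cbind(df, as.data.frame(t(featureMatrix(m))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#'
#' @param path a CSV written by \code{\link{writeFeatureMatrix}} (or of the
#'   same layout).
#' @return an \linkS4class{HRVWindowMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("window_start_s", "window_end_s")
  if (!all(need %in% colnames(df)))
    stop("feature CSV must contain window_start_s and window_end_s")
  meta <- intersect(c(need, "y", "question_id"), colnames(df))
  featCols <- setdiff(colnames(df), meta)
  m <- t(as.matrix(df[, featCols, drop = FALSE]))
  HRVWindowMatrix(m, df$window_start_s, df$window_end_s,
                  y = if ("y" %in% meta) df$y else NA_real_,
                  questionId = if ("question_id" %in% meta) df$question_id
                               else NA_character_)
}

#' Write an equivalence report (CSV + JSON summary)
#'
#' @param report an \linkS4class{EquivalenceReport}.
#' @param csvPath per-parameter CSV output path.
#' @param jsonPath optional JSON summary path (percent similar, effect
#'   size, pair count).
#' @return invisibly, the paths written.
#' @export
writeEquivalenceReport <- function(report, csvPath, jsonPath = NULL) {
  stopifnot(is(report, "EquivalenceReport"))
  write.csv(report@results, csvPath, row.names = FALSE)
  out <- csvPath
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(percent_similar = percentSimilar(report),
           effect_size = report@effectSize, n_pairs = report@nPairs),
      jsonPath, auto_unbox = TRUE, digits = NA)
    out <- c(out, jsonPath)
  }
  invisible(out)
}

#' Published cross-modality equivalence markers
#'
#' The encoded significance-marker columns of the published cross-device
#' HRV validation tables (one row per canonical parameter, one column per
#' modality comparison), shipped as plain text under
#' \code{inst/extdata/equivalence_markers.csv}. Used to validate the
#' percent-similar arithmetic.
#'
#' @return data.frame: \code{parameter} plus one marker column per
#'   comparison (\code{bidmc}, \code{capnobase}, \code{perform_af},
#'   \code{perform_non_af}, \code{wesad}, \code{ecg_ppg}, \code{ecg_rppg},
#'   \code{ppg_rppg}).
#' @export
referenceMarkerTables <- function() {
  path <- system.file("extdata", "equivalence_markers.csv",
                      package = "lierhrv", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
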