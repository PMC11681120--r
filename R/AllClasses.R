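#' @import methods
#' @importFrom stats sd approx median pt rnorm predict
#' @importFrom utils read.csv write.csv
NULL

#' RawSignal: a single-channel physiological waveform
#'
#' Container for an evenly sampled one-dimensional signal (ECG-like or
#' pulse-like) together with its sampling rate. All beat detectors in the
#' package take a \code{RawSignal}.
#'
#' @slot samples numeric vector of amplitudes (arbitrary units).
#' @slot samplingRate sampling frequency in Hz (finite, > 0).
#' @slot modality either \code{"ecg"} or \code{"pulse"}.
#' @slot startTime time of the first sample in seconds (default 0).
#' @export
setClass("RawSignal",
  representation(samples = "numeric", samplingRate = "numeric",
                 modality = "character", startTime = "numeric"),
  prototype(modality = "pulse", startTime = 0),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) < 2L)
      msg <- c(msg, "signal must contain at least 2 samples")
    if (any(!is.finite(object@samples)))
      msg <- c(msg, "signal contains non-finite samples")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single finite positive number")
    if (!object@modality %in% c("ecg", "pulse"))
      msg <- c(msg, "modality must be 'ecg' or 'pulse'")
    if (length(msg)) msg else TRUE
  })

#' Construct a RawSignal
#'
#' @param samples numeric amplitude vector (at least 2 finite values).
#' @param samplingRate sampling frequency in Hz.
#' @param modality \code{"ecg"} or \code{"pulse"}.
#' @param startTime record start time in seconds.
#' @return A \linkS4class{RawSignal} object.
#' @examples
#' sig <- RawSignal(sin(seq(0, 10, by = 0.005)), samplingRate = 200)
#' @export
RawSignal <- function(samples, samplingRate, modality = "pulse", startTime = 0) {
  new("RawSignal", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      modality = modality, startTime = as.numeric(startTime))
}

#' @describeIn RawSignal-class number of samples
#' @param x a RawSignal
#' @export
setMethod("length", "RawSignal", function(x) length(x@samples))

setMethod("show", "RawSignal", function(object) {
  cat(sprintf("RawSignal (%s): %d samples at %g Hz (%.1f s)\n",
              object@modality, length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate))
})

#' BeatSeries: ordered beat times and the derived NN-interval series
#'
#' The universal intermediate between beat detection and HRV extraction.
#' Beat times are stored in seconds from record start; NN intervals are
#' derived (never stored) as successive differences in milliseconds, so the
#' two representations can never drift apart.
#'
#' @slot beatTimes strictly increasing beat times in seconds.
#' @export
setClass("BeatSeries",
  representation(beatTimes = "numeric"),
  validity = function(object) {
    bt <- object@beatTimes
    if (any(!is.finite(bt)))
      return("beat times must be finite")
    if (length(bt) >= 2L && any(diff(bt) <= 0))
      return("beat times must be strictly increasing")
    TRUE
  })

#' Construct a BeatSeries from beat times
#'
#' @param beatTimes strictly increasing numeric vector of beat times
#'   (seconds).
#' @return A \linkS4class{BeatSeries}.
#' @examples
#' b <- BeatSeries(seq(0, 60, by = 0.9))
#' head(nnIntervals(b))
#' @export
BeatSeries <- function(beatTimes = numeric()) {
  new("BeatSeries", beatTimes = as.numeric(beatTimes))
}

#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))
#' @describeIn BeatSeries-class beat times in seconds
#' @param x a BeatSeries
#' @export
setMethod("beatTimes", "BeatSeries", function(x) x@beatTimes)

#' @export
setGeneric("nnIntervals", function(x) standardGeneric("nnIntervals"))
#' @describeIn BeatSeries-class NN intervals in milliseconds
#' @export
setMethod("nnIntervals", "BeatSeries", function(x) diff(x@beatTimes) * 1000)

#' @describeIn BeatSeries-class number of beats
#' @export
setMethod("length", "BeatSeries", function(x) length(x@beatTimes))

setMethod("show", "BeatSeries", function(object) {
  n <- length(object@beatTimes)
  if (n == 0L) {
    cat("BeatSeries: empty\n")
  } else {
    cat(sprintf("BeatSeries: %d beats over %.1f s (mean NN %.1f ms)\n",
                n, diff(range(object@beatTimes)),
                if (n > 1) mean(diff(object@beatTimes)) * 1000 else NA_real_))
  }
})

#' HRVWindowMatrix: per-window HRV feature vectors
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"features"} holds
#' one column per analysis window and one row per HRV parameter (the 39
#' canonical parameters by default, in \code{\link{hrvFeatureNames}} order).
#' \code{colData} carries \code{windowStart}, \code{windowEnd} (seconds),
#' \code{nBeats}, and for labelled active-state windows \code{y} (1 = truth,
#' 0 = lie) and \code{questionId}. \code{rowData} carries the \code{longTerm}
#' flag for parameters that require a long (>= 5-min) analysis window.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
setClass("HRVWindowMatrix", contains = "SummarizedExperiment")

#' Construct an HRVWindowMatrix
#'
#' @param features numeric matrix, features x windows; rownames are feature
#'   names.
#' @param windowStart,windowEnd numeric vectors of window boundaries in
#'   seconds, one per column.
#' @param nBeats optional integer vector of beats per window.
#' @param y optional binary label per window (1 truth, 0 lie).
#' @param questionId optional question identifier per window.
#' @return An \linkS4class{HRVWindowMatrix}.
#' @export
HRVWindowMatrix <- function(features, windowStart, windowEnd,
                            nBeats = NA_integer_, y = NA_real_,
                            questionId = NA_character_) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    stop("feature matrix must have rownames")
  nw <- ncol(features)
  cd <- S4Vectors::DataFrame(
    windowStart = rep_len(as.numeric(windowStart), nw),
    windowEnd = rep_len(as.numeric(windowEnd), nw),
    nBeats = rep_len(as.integer(nBeats), nw),
    y = rep_len(as.numeric(y), nw),
    questionId = rep_len(as.character(questionId), nw))
  rd <- S4Vectors::DataFrame(longTerm = rownames(features) %in% longTermFeatures())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features), colData = cd, rowData = rd)
  new("HRVWindowMatrix", se)
}

setValidity("HRVWindowMatrix", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("windowStart", "windowEnd") %in% colnames(cd)))
    return("colData must contain windowStart and windowEnd")
  ws <- cd$windowStart
  if (length(ws) >= 2L && any(diff(ws) <= 0))
    return("window start times must be strictly increasing")
  TRUE
})

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @describeIn HRVWindowMatrix-class the features x windows matrix
#' @param x an HRVWindowMatrix
#' @export
setMethod("featureMatrix", "HRVWindowMatrix",
          function(x) SummarizedExperiment::assay(x, "features"))

#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @describeIn HRVWindowMatrix-class window start times (s)
#' @export
setMethod("windowStarts", "HRVWindowMatrix",
          function(x) SummarizedExperiment::colData(x)$windowStart)

#' @export
setGeneric("windowEnds", function(x) standardGeneric("windowEnds"))
#' @describeIn HRVWindowMatrix-class window end times (s)
#' @export
setMethod("windowEnds", "HRVWindowMatrix",
          function(x) SummarizedExperiment::colData(x)$windowEnd)

#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @describeIn HRVWindowMatrix-class binary truth/lie labels (1 truth, 0 lie)
#' @export
setMethod("windowLabels", "HRVWindowMatrix",
          function(x) SummarizedExperiment::colData(x)$y)

setMethod("show", "HRVWindowMatrix", function(object) {
  cat(sprintf("HRVWindowMatrix: %d features x %d windows\n",
              nrow(object), ncol(object)))
  if (ncol(object) > 0) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("  windows span %.1f-%.1f s", min(cd$windowStart),
                max(cd$windowEnd)))
    if (any(!is.na(cd$y)))
      cat(sprintf("; labels: %d truth / %d lie", sum(cd$y == 1, na.rm = TRUE),
                  sum(cd$y == 0, na.rm = TRUE)))
    cat("\n")
  }
})

#' EquivalenceReport: per-parameter TOST results and percent-similar summary
#'
#' @slot results data.frame with one row per parameter: \code{parameter},
#'   \code{n}, \code{meanDiff}, \code{sdDiff}, \code{pLower}, \code{pUpper},
#'   \code{marker}, \code{equivalent}, \code{note}.
#' @slot effectSize Cohen's d used for the equivalence margins.
#' @slot nPairs number of paired windows used.
#' @export
setClass("EquivalenceReport",
  representation(results = "data.frame", effectSize = "numeric",
                 nPairs = "integer"))

#' @export
setGeneric("percentSimilar", function(x, ...) standardGeneric("percentSimilar"))

#' @describeIn EquivalenceReport-class percent of the parameter rows declared
#'   equivalent (marker other than \code{"-"}); the denominator is the full
#'   row count even when some parameters were not computable.
#' @param x an EquivalenceReport
#' @param ... unused
#' @export
setMethod("percentSimilar", "EquivalenceReport", function(x, ...) {
  res <- x@results
  if (all(is.na(res$marker))) return(NA_real_)
  100 * sum(res$marker != "-", na.rm = TRUE) / nrow(res)
})

setMethod("show", "EquivalenceReport", function(object) {
  res <- object@results
  cat(sprintf("EquivalenceReport: %d parameters, effect size d = %g, N = %d pairs\n",
              nrow(res), object@effectSize, object@nPairs))
  cat(sprintf("  percent similar: %s\n",
              ifelse(is.na(percentSimilar(object)), "not computable",
                     sprintf("%.2f%%", percentSimilar(object)))))
  mk <- ifelse(is.na(res$marker), "?", res$marker)
  for (i in seq_len(nrow(res)))
    cat(sprintf("  %-12s %s\n", res$parameter[i], mk[i]))
  invisible(NULL)
})
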