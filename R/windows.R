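#' Sliding-window configuration for HRV extraction
#'
#' Two stepping modes are supported: \code{"time_overlap"} (fixed-length
#' windows advanced by \code{windowLength - overlap} seconds, e.g. 1-min
#' windows with 30-s overlap) and \code{"beat_step"} (fixed-length windows
#' whose start is anchored on a beat and advanced by \code{stepBeats}
#' beats, e.g. the 30-s / 2-beat-step windows of the lie-detection
#' pipeline).
#'
#' @param windowLength window length in seconds (> 0).
#' @param stepMode \code{"time_overlap"} or \code{"beat_step"}.
#' @param overlap overlap in seconds (time_overlap mode; must be smaller
#'   than \code{windowLength}).
#' @param stepBeats step in beats (beat_step mode; >= 1).
#' @param minBeats windows containing fewer beats are dropped (>= 4).
#' @return a list of class \code{"HRVWindowConfig"}.
#' @examples
#' hrvWindowConfig(60, "time_overlap", overlap = 30)
#' hrvWindowConfig(30, "beat_step", stepBeats = 2)
#' @export
hrvWindowConfig <- function(windowLength = 60,
                            stepMode = c("time_overlap", "beat_step"),
                            overlap = 30, stepBeats = 2, minBeats = 10) {
  stepMode <- match.arg(stepMode)
  if (windowLength <= 0) stop("windowLength must be positive")
  if (stepMode == "time_overlap" && overlap >= windowLength)
    stop("overlap must be smaller than windowLength")
  if (stepMode == "beat_step" && stepBeats < 1)
    stop("stepBeats must be >= 1")
  if (minBeats < 4) stop("minBeats must be >= 4")
  structure(list(windowLength = windowLength, stepMode = stepMode,
                 overlap = overlap, stepBeats = as.integer(stepBeats),
                 minBeats = as.integer(minBeats)),
            class = "HRVWindowConfig")
}

#' Segment a BeatSeries into analysis windows
#'
#' Windows are half-open \code{[start, start + windowLength)}: a beat
#' exactly on the right edge belongs to the next window. Windows with fewer
#' than \code{minBeats} beats are dropped (with a message). A window is
#' emitted only when it fits inside the recorded span.
#'
#' @param beats a \linkS4class{BeatSeries}.
#' @param config an \code{\link{hrvWindowConfig}}.
#' @return a list of \linkS4class{BeatSeries}, each carrying
#'   \code{windowStart} / \code{windowEnd} attributes (seconds); empty (with
#'   a warning) when the record is shorter than one window.
#' @export
segmentWindows <- function(beats, config = hrvWindowConfig()) {
  stopifnot(is(beats, "BeatSeries"), inherits(config, "HRVWindowConfig"))
  bt <- beatTimes(beats)
  L <- config$windowLength
  eps <- 1e-9
  if (length(bt) < 2L || diff(range(bt)) + eps < L) {
    warning("record shorter than one window; no windows produced")
    return(list())
  }
  spanEnd <- bt[length(bt)]
  if (config$stepMode == "time_overlap") {
    step <- L - config$overlap
    starts <- seq(bt[1], spanEnd, by = step)
    starts <- starts[starts + L <= spanEnd + eps]
  } else {
    anchor <- seq(1L, length(bt), by = config$stepBeats)
    starts <- bt[anchor]
    starts <- starts[starts + L <= spanEnd + eps]
  }
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  nDropped <- 0L
  for (i in seq_along(starts)) {
    s <- starts[i]
    sel <- bt >= s - eps & bt < s + L - eps
    if (sum(sel) >= config$minBeats) {
      w <- BeatSeries(bt[sel])
      attr(w, "windowStart") <- s
      attr(w, "windowEnd") <- s + L
      out[[i]] <- w
      keep[i] <- TRUE
    } else nDropped <- nDropped + 1L
  }
  if (nDropped > 0L)
    message(sprintf("segmentWindows: dropped %d window(s) with fewer than %d beats",
                    nDropped, config$minBeats))
  out[keep]
}
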