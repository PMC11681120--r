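#' Compute one HRV feature vector from a window of beats
#'
#' Evaluates all 39 canonical parameters on a single window. Long-term
#' parameters (\code{\link{longTermFeatures}}) are computed only when
#' \code{windowLength >= 300} seconds; otherwise they are NA. Individual
#' parameter failures (too few beats, degenerate data) flag that parameter
#' NA and never abort the window.
#'
#' @param beats a \linkS4class{BeatSeries} window.
#' @param windowLength nominal window length in seconds (gates the
#'   long-term parameters).
#' @param bands frequency bands, see \code{\link{hrvBands}}.
#' @return named numeric vector in \code{\link{hrvFeatureNames}} order.
#' @export
hrvFeatureVector <- function(beats, windowLength, bands = hrvBands()) {
  nn <- nnIntervals(beats)
  out <- stats::setNames(rep(NA_real_, 39L), hrvFeatureNames())
  td <- timeDomain(nn)
  out[names(td)] <- td
  fr <- fragmentation(nn)
  out[names(fr)] <- fr
  pc <- poincare(nn)
  out[names(pc)] <- pc
  fd <- frequencyDomain(beats, bands)
  out[names(fd)] <- fd
  df <- dfa(nn)
  out[names(df)] <- df
  ms <- mse(nn)
  out[names(ms)] <- ms
  lt <- longTermFeatures()
  if (windowLength < 300) out[lt] <- NA_real_
  out
}

#' Extract HRV parameters over sliding windows
#'
#' Segments the beat series per \code{config} and computes the 39 canonical
#' HRV parameters in every retained window. One not-computable parameter
#' never discards a window.
#'
#' @param beats a \linkS4class{BeatSeries}.
#' @param config an \code{\link{hrvWindowConfig}}; the defaults are 1-min
#'   windows with 30-s overlap.
#' @param bands frequency bands, see \code{\link{hrvBands}}.
#' @return an \linkS4class{HRVWindowMatrix} (features x windows); empty,
#'   with a warning, when no window fits.
#' @examples
#' b <- simulateRR(simulationConfig(duration = 300, seed = 1))
#' m <- extractHRV(b, hrvWindowConfig(60, "time_overlap", overlap = 30))
#' featureMatrix(m)[1:5, 1:3]
#' @export
extractHRV <- function(beats, config = hrvWindowConfig(), bands = hrvBands()) {
  wins <- segmentWindows(beats, config)
  if (!length(wins)) {
    return(HRVWindowMatrix(
      matrix(numeric(), nrow = 39L, ncol = 0L,
             dimnames = list(hrvFeatureNames(), NULL)),
      windowStart = numeric(), windowEnd = numeric()))
  }
  feat <- vapply(wins, hrvFeatureVector, numeric(39L),
                 windowLength = config$windowLength, bands = bands)
  rownames(feat) <- hrvFeatureNames()
  HRVWindowMatrix(feat,
                  windowStart = vapply(wins, attr, numeric(1), "windowStart"),
                  windowEnd = vapply(wins, attr, numeric(1), "windowEnd"),
                  nBeats = vapply(wins, length, integer(1)))
}
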