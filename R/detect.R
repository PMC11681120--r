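## Beat detection: AMPD multiscale peak detection, an energy-based QRS
## detector, detector-agreement fusion, and peak-to-interval conversion.

#' Automatic multiscale-based peak detection (AMPD)
#'
#' Detects local maxima that persist across all window scales up to the
#' scale with the richest local-maxima structure. The signal is linearly
#' detrended, a local-maxima scalogram is built over scales
#' \eqn{k = 1, \dots, L} (sample \eqn{i} is a maximum at scale \eqn{k} when
#' \eqn{x_i > x_{i-k}} and \eqn{x_i > x_{i+k}}), the scale \eqn{\lambda}
#' minimising the row-wise count of non-maxima is selected, and the peaks
#' are the samples that are maxima at every scale \eqn{k \le \lambda}.
#' This is the deterministic form of the algorithm: the random entries of
#' the original scalogram only perturb ties and are omitted.
#'
#' @param signal a \linkS4class{RawSignal}.
#' @param maxScale largest window scale \eqn{L} in samples, or
#'   \code{"auto"} (the default), which caps \eqn{L} at two seconds' worth
#'   of samples -- comfortably above half of any physiological beat
#'   interval -- or at \code{(length - 2) / 2} for short records.
#' @return integer vector of peak sample indices (1-based), strictly
#'   increasing; empty when the detrended signal has no persistent maxima
#'   (e.g. a constant or monotone signal).
#' @examples
#' t <- seq(0, 10, by = 1 / 200)
#' sig <- RawSignal(sin(2 * pi * t), 200)
#' detectPeaksAMPD(sig)
#' @export
detectPeaksAMPD <- function(signal, maxScale = "auto") {
  stopifnot(is(signal, "RawSignal"))
  x <- signal@samples
  n <- length(x)
  if (identical(maxScale, "auto")) {
    maxScale <- min(floor((n - 2) / 2), ceiling(2 * signal@samplingRate))
  }
  maxScale <- as.integer(maxScale)
  if (is.na(maxScale) || maxScale < 1L)
    stop("maxScale must be a positive integer")
  if (n < 2L * maxScale + 2L)
    stop("signal too short for the requested maxScale")

  x <- detrendLinear(x)
  if (max(x) - min(x) < .Machine$double.eps * max(1, max(abs(x))))
    return(integer())

  ## pass 1: per-scale count of non-maxima (the deterministic row sum)
  gamma <- integer(maxScale)
  for (k in seq_len(maxScale)) {
    idx <- (k + 1L):(n - k)
    ismax <- x[idx] > x[idx - k] & x[idx] > x[idx + k]
    gamma[k] <- n - sum(ismax)
  }
  lambda <- which.min(gamma)

  ## pass 2: samples that are maxima at every scale <= lambda; a
  ## comparison falling outside the record is vacuously satisfied so that
  ## peaks within lambda samples of the edges are not lost
  idx <- 2L:(n - 1L)  # endpoints have no two-sided neighbourhood
  keep <- rep(TRUE, length(idx))
  for (k in seq_len(lambda)) {
    left <- idx - k; right <- idx + k
    okL <- left < 1L | x[idx] > x[pmax(left, 1L)]
    okR <- right > n | x[idx] > x[pmin(right, n)]
    keep <- keep & okL & okR
  }
  idx[keep]
}

detrendLinear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc * tc)
  x - mean(x) - slope * tc
}

#' Energy-based R-peak detection for ECG-like signals
#'
#' A stand-in QRS detector: band-pass filtering, squaring, moving-window
#' energy integration, block-adaptive thresholding and refractory
#' enforcement. Each detection region is mapped back to the raw signal and
#' the local amplitude maximum is reported.
#'
#' @param signal a \linkS4class{RawSignal}.
#' @param band numeric length-2, band-pass edges in Hz (default 5-25 Hz,
#'   the usual QRS energy band).
#' @param refractory minimum separation between reported peaks in seconds
#'   (default 0.25 s).
#' @param integrationWindow moving-average window for the energy signal in
#'   seconds (default 0.15 s).
#' @return integer vector of peak sample indices, strictly increasing and
#'   separated by at least \code{refractory}.
#' @export
detectRPeaksEnergy <- function(signal, band = c(5, 25), refractory = 0.25,
                               integrationWindow = 0.15) {
  stopifnot(is(signal, "RawSignal"))
  if (length(band) != 2L || !all(is.finite(band)) || band[1] >= band[2])
    stop("band edges must be strictly increasing")
  if (refractory <= 0) stop("refractory must be positive")
  fs <- signal@samplingRate
  if (fs < 2 * band[2])
    stop("sampling rate must be at least twice the upper band edge")
  x <- signal@samples
  n <- length(x)
  if (n < 2 * fs) stop("signal shorter than 2 s")

  bf <- signal::butter(3, band * 2 / fs, type = "pass")
  xf <- signal::filtfilt(bf, x)
  energy <- xf^2
  w <- max(1L, round(integrationWindow * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  gmax <- max(integ)
  if (gmax <= 0) return(integer())

  ## block-adaptive threshold: 30% of the local 10-s block maximum, with a
  ## global floor so silent stretches cannot fire
  blockLen <- max(1L, round(10 * fs))
  nBlocks <- ceiling(n / blockLen)
  thr <- numeric(n)
  for (b in seq_len(nBlocks)) {
    i0 <- (b - 1L) * blockLen + 1L
    i1 <- min(n, b * blockLen)
    thr[i0:i1] <- max(0.3 * max(integ[i0:i1]), 0.05 * gmax)
  }
  above <- integ > thr
  if (!any(above)) return(integer())

  ## detection regions -> local raw-amplitude maxima
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  half <- max(1L, round(integrationWindow * fs / 2))
  cand <- apply(regions, 1, function(rg) {
    c0 <- rg[1] + which.max(integ[rg[1]:rg[2]]) - 1L
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    lo + which.max(x[lo:hi]) - 1L
  })
  cand <- sort(unique(cand))

  ## refractory: within a conflict keep the larger raw amplitude
  refSamp <- refractory * fs
  keep <- integer()
  for (p in cand) {
    if (length(keep) && (p - keep[length(keep)]) < refSamp) {
      if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  keep
}

#' Agreement fusion of two peak detectors
#'
#' Returns the subset of primary-detector peaks that are confirmed by a
#' secondary-detector peak within \code{tolerance}. Matching is greedy
#' nearest-first and one-to-one: each secondary peak confirms at most one
#' primary peak. The primary detector's timestamps are the ones kept.
#'
#' @param primary,secondary strictly increasing integer vectors of peak
#'   sample indices.
#' @param tolerance matching tolerance in seconds (default 0.15 s).
#' @param samplingRate sampling rate in Hz used to convert the tolerance to
#'   samples.
#' @return integer vector: the confirmed subset of \code{primary}, sorted.
#' @export
fuseDetections <- function(primary, secondary, tolerance = 0.15,
                           samplingRate) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (length(primary) >= 2L && any(diff(primary) <= 0))
    stop("primary peak list must be strictly increasing")
  if (length(secondary) >= 2L && any(diff(secondary) <= 0))
    stop("secondary peak list must be strictly increasing")
  if (!length(primary) || !length(secondary)) return(integer())
  tolSamp <- tolerance * samplingRate

  d <- abs(outer(primary, secondary, "-"))
  pairs <- which(d <= tolSamp, arr.ind = TRUE)
  if (!nrow(pairs)) return(integer())
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  usedP <- logical(length(primary)); usedS <- logical(length(secondary))
  matched <- integer()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!usedP[i] && !usedS[j]) {
      usedP[i] <- TRUE; usedS[j] <- TRUE
      matched <- c(matched, primary[i])
    }
  }
  sort(matched)
}

#' Convert peak indices to a BeatSeries
#'
#' Beat times are \code{(index - 1) / samplingRate} seconds (the first
#' sample of the record is time 0); NN intervals follow in milliseconds.
#'
#' @param peaks strictly increasing integer vector of peak sample indices
#'   (1-based), at least 2.
#' @param samplingRate sampling rate in Hz.
#' @return A \linkS4class{BeatSeries}.
#' @examples
#' peaksToIntervals(c(1, 201, 401), 200)  # two 1000-ms intervals
#' @export
peaksToIntervals <- function(peaks, samplingRate) {
  if (length(peaks) < 2L) stop("need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peak indices must be strictly increasing")
  if (samplingRate <= 0 || !is.finite(samplingRate))
    stop("samplingRate must be finite and positive")
  BeatSeries((as.numeric(peaks) - 1) / samplingRate)
}

#' Detect beats in a raw signal
#'
#' Convenience front end: AMPD for pulse-like signals; for ECG-like signals
#' the energy detector, optionally fused (agreement) with AMPD as the
#' confirming detector.
#'
#' @param signal a \linkS4class{RawSignal}.
#' @param fuse for ECG, require agreement between the energy detector and
#'   AMPD (default TRUE).
#' @param tolerance agreement tolerance in seconds.
#' @return A \linkS4class{BeatSeries}.
#' @export
detectBeats <- function(signal, fuse = TRUE, tolerance = 0.15) {
  stopifnot(is(signal, "RawSignal"))
  if (signal@modality == "pulse") {
    peaks <- detectPeaksAMPD(signal)
  } else {
    peaks <- detectRPeaksEnergy(signal)
    if (fuse) {
      conf <- detectPeaksAMPD(signal)
      peaks <- fuseDetections(peaks, conf, tolerance, signal@samplingRate)
    }
  }
  peaksToIntervals(peaks, signal@samplingRate)
}
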