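#' Canonical HRV parameter names
#'
#' The 39 HRV parameters computed per window, in canonical (report) order:
#' time domain (AVNN, SDNN, RMSSD, SEM, PNN50), heart-rate fragmentation
#' (PIP, IALS, PSS, PAS), frequency domain (HF/LF/VLF norms, peaks and
#' powers, LF/HF ratio, total power, the log-log spectral slope BETA),
#' Poincare (SD1, SD2), detrended fluctuation analysis (ALPHA1, ALPHA2) and
#' multiscale entropy at scales 1 through 15 (MSE1..MSE15).
#'
#' This ordering is also the tie-break order used by
#' \code{\link{selectFeatures}}.
#'
#' @return character vector of length 39.
#' @examples
#' hrvFeatureNames()
#' @export
hrvFeatureNames <- function() {
  c("AVNN", "SDNN", "RMSSD", "SEM", "PNN50",
    "PIP", "IALS", "PSS", "PAS",
    "HF_NORM", "HF_PEAK", "HF_POWER",
    "LF_NORM", "LF_PEAK", "LF_POWER",
    "LF_HF", "VLF_NORM", "VLF_POWER", "TOTAL_POWER", "BETA",
    "SD1", "SD2", "ALPHA1", "ALPHA2",
    paste0("MSE", 1:15))
}

#' Long-term HRV parameters
#'
#' Parameters whose definition needs more data than a short (<= 1-min)
#' window supplies: the VLF band (support below 0.04 Hz), total power and
#' the spectral slope BETA (both VLF-dependent), the large-box DFA slope
#' ALPHA2 (boxes of 16-64 intervals) and MSE scales 7-15 (a scale-s entropy
#' needs on the order of 10 x s intervals). These are computed only when the
#' analysis window is at least 300 s long; in shorter windows they are
#' flagged not-computable.
#'
#' @return character vector, a subset of \code{\link{hrvFeatureNames}}.
#' @seealso \code{\link{shortTermFeatures}}
#' @export
longTermFeatures <- function() {
  c("VLF_NORM", "VLF_POWER", "TOTAL_POWER", "BETA", "ALPHA2",
    paste0("MSE", 7:15))
}

#' Short-term HRV parameters
#'
#' The complement of \code{\link{longTermFeatures}} within the canonical 39;
#' the lie-detection pipeline restricts feature selection to this set
#' because the physiological response to a question is brief.
#'
#' @return character vector of the 25 short-term parameter names.
#' @export
shortTermFeatures <- function() {
  setdiff(hrvFeatureNames(), longTermFeatures())
}
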