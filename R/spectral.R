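## Frequency-domain HRV on the unevenly sampled NN series via the
## Lomb-Scargle periodogram (no resampling).

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic Lomb normalisation with the time-offset tau; returned as a
#' one-sided spectral density so that the integral over frequency
#' approximates the series variance: \code{density = 2 * mean(dt) * P(f)}
#' where \code{P} is the raw Lomb power.
#'
#' @param times sample times in seconds (strictly increasing).
#' @param values sample values (here NN intervals in ms, so the density is
#'   in ms^2/Hz).
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return list with \code{freq} (Hz) and \code{density} (value^2 / Hz).
#' @export
lombPeriodogram <- function(times, values, freqs) {
  n <- length(times)
  stopifnot(n == length(values), n >= 4L)
  y <- values - mean(values)
  dtMean <- mean(diff(times))
  dens <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    arg <- w * (times - tau)
    cw <- cos(arg); sw <- sin(arg)
    p <- 0.5 * (sum(y * cw)^2 / sum(cw^2) + sum(y * sw)^2 / sum(sw^2))
    2 * dtMean * p
  }, numeric(1))
  list(freq = freqs, density = dens)
}

#' Standard HRV frequency bands (Hz)
#'
#' VLF 0.003-0.04, LF 0.04-0.15, HF 0.15-0.4 Hz.
#' @return named list of length-2 numeric vectors.
#' @export
hrvBands <- function() {
  list(VLF = c(0.003, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4))
}

#' Frequency-domain HRV parameters from a window of beats
#'
#' Estimates the NN spectrum with \code{\link{lombPeriodogram}} on a
#' frequency grid from \code{1 / span} to the HF upper edge (oversampling
#' factor 4), integrates band powers by the trapezoid rule, and derives
#' normalised powers, in-band peak frequencies, the LF/HF ratio, total
#' power and the log-log spectral slope BETA (least-squares slope of
#' log10 density vs log10 frequency for frequencies at or below the VLF
#' upper edge). Norms are computed against LF + HF, so
#' \code{LF_NORM + HF_NORM == 100} whenever both are computable.
#'
#' A band with fewer than two supported grid frequencies (window too short)
#' is flagged NA. A constant NN series yields zero powers and NA peaks.
#'
#' @param beats a \linkS4class{BeatSeries} (window).
#' @param bands band edges as from \code{\link{hrvBands}}.
#' @param oversample frequency-grid oversampling factor (default 4).
#' @return named vector: \code{VLF_POWER}, \code{LF_POWER}, \code{HF_POWER}
#'   (ms^2), \code{VLF_NORM}, \code{LF_NORM}, \code{HF_NORM} (percent of
#'   LF+HF), \code{LF_PEAK}, \code{HF_PEAK} (Hz), \code{LF_HF},
#'   \code{TOTAL_POWER} (ms^2), \code{BETA}.
#' @export
frequencyDomain <- function(beats, bands = hrvBands(), oversample = 4) {
  out <- c(VLF_POWER = NA_real_, LF_POWER = NA_real_, HF_POWER = NA_real_,
           VLF_NORM = NA_real_, LF_NORM = NA_real_, HF_NORM = NA_real_,
           LF_PEAK = NA_real_, HF_PEAK = NA_real_, LF_HF = NA_real_,
           TOTAL_POWER = NA_real_, BETA = NA_real_)
  bt <- beatTimes(beats)
  if (length(bt) < 5L) return(out)
  nn <- nnIntervals(beats)
  tm <- bt[-1]  # each interval stamped at its terminating beat
  span <- tm[length(tm)] - tm[1]
  if (span <= 0) return(out)
  fmin <- 1 / span
  fmax <- bands$HF[2]
  if (fmin >= fmax) return(out)
  df <- fmin / oversample
  freqs <- seq(fmin, fmax, by = df)

  if (stats::var(nn) <= .Machine$double.eps) {
    out[c("VLF_POWER", "LF_POWER", "HF_POWER")] <- 0
    return(out)
  }
  sp <- lombPeriodogram(tm, nn, freqs)

  bandStats <- lapply(bands, function(b) {
    sel <- sp$freq >= b[1] & sp$freq <= b[2]
    if (sum(sel) < 2L) return(list(power = NA_real_, peak = NA_real_))
    f <- sp$freq[sel]; d <- sp$density[sel]
    power <- sum(diff(f) * (d[-1] + d[-length(d)]) / 2)
    list(power = power, peak = f[which.max(d)])
  })
  vlf <- bandStats$VLF$power; lf <- bandStats$LF$power; hf <- bandStats$HF$power
  out["VLF_POWER"] <- vlf
  out["LF_POWER"] <- lf
  out["HF_POWER"] <- hf
  out["LF_PEAK"] <- bandStats$LF$peak
  out["HF_PEAK"] <- bandStats$HF$peak
  if (is.finite(lf) && is.finite(hf) && (lf + hf) > 0) {
    out["LF_NORM"] <- 100 * lf / (lf + hf)
    out["HF_NORM"] <- 100 * hf / (lf + hf)
    if (is.finite(vlf)) out["VLF_NORM"] <- 100 * vlf / (lf + hf)
    if (hf > 0) out["LF_HF"] <- lf / hf
  }
  if (is.finite(vlf)) out["TOTAL_POWER"] <- vlf + lf + hf

  selB <- sp$freq <= bands$VLF[2] & sp$density > 0
  if (sum(selB) >= 2L) {
    lx <- log10(sp$freq[selB]); ly <- log10(sp$density[selB])
    out["BETA"] <- sum((lx - mean(lx)) * (ly - mean(ly))) /
      sum((lx - mean(lx))^2)
  }
  out
}
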