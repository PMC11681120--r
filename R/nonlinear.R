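## Nonlinear HRV parameters: detrended fluctuation analysis and multiscale
## (sample) entropy.

#' Detrended fluctuation analysis slopes
#'
#' DFA-1: the interval series is centred and integrated into a profile, the
#' profile is cut into non-overlapping boxes of size \eqn{n}, each box is
#' linearly detrended, and \eqn{F(n)} is the root-mean-square residual.
#' \code{ALPHA1} is the least-squares slope of \eqn{\log F(n)} vs
#' \eqn{\log n} over box sizes 4-15 and \code{ALPHA2} over 16-64. Box sizes
#' with fewer than two complete boxes are skipped; a slope is NA when fewer
#' than three box sizes remain or when the fluctuations are degenerate
#' (\eqn{F(n) = 0}, e.g. a constant series).
#'
#' @param nn numeric vector of NN intervals (ms). At least 16 intervals for
#'   ALPHA1, about 70 for ALPHA2.
#' @return named vector \code{ALPHA1}, \code{ALPHA2} (dimensionless).
#' @export
dfa <- function(nn) {
  N <- length(nn)
  c(ALPHA1 = if (N >= 16L) dfaSlope(nn, 4:15) else NA_real_,
    ALPHA2 = if (N >= 70L) dfaSlope(nn, 16:64) else NA_real_)
}

dfaSlope <- function(nn, boxSizes) {
  N <- length(nn)
  boxSizes <- boxSizes[floor(N / boxSizes) >= 2L]
  if (length(boxSizes) < 3L) return(NA_real_)
  y <- cumsum(nn - mean(nn))
  Fn <- vapply(boxSizes, function(b) {
    nb <- floor(N / b)
    res2 <- 0
    t <- seq_len(b)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    for (k in seq_len(nb)) {
      seg <- y[((k - 1L) * b + 1L):(k * b)]
      slope <- sum(tc * seg) / stt
      r <- seg - mean(seg) - slope * tc
      res2 <- res2 + sum(r^2)
    }
    sqrt(res2 / (nb * b))
  }, numeric(1))
  if (any(Fn <= 0)) return(NA_real_)
  lx <- log(boxSizes); ly <- log(Fn)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Sample entropy
#'
#' \code{SampEn(m, r)} = negative log of the conditional probability that
#' two sequences matching for \code{m} points (Chebyshev distance <= r,
#' self-matches excluded) also match for \code{m + 1}. Template pairs are
#' counted over \code{i < j} with \code{i, j <= N - m}.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r tolerance, in the units of \code{x}.
#' @return sample entropy; 0 for a constant series; NA when no template
#'   pair matches at dimension \code{m + 1} (entropy unbounded) or when the
#'   series is too short.
#' @export
sampleEntropy <- function(x, m = 2L, r) {
  N <- length(x)
  if (N < m + 2L || !is.finite(r) || r < 0) return(NA_real_)
  nT <- N - m
  A <- 0; B <- 0
  for (i in seq_len(nT - 1L)) {
    js <- (i + 1L):nT
    ok <- rep(TRUE, length(js))
    for (k in 0L:(m - 1L))
      ok <- ok & abs(x[i + k] - x[js + k]) <= r
    B <- B + sum(ok)
    ok <- ok & abs(x[i + m] - x[js + m]) <= r
    A <- A + sum(ok)
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Multiscale entropy
#'
#' Coarse-grains the NN series by non-overlapping means at each scale and
#' computes sample entropy with embedding \code{m} and a tolerance fixed at
#' \code{rFactor} times the sample standard deviation of the original
#' (scale-1) series. Scale \code{s} requires at least \code{10 * s}
#' intervals; shorter input flags that scale NA.
#'
#' @param nn numeric vector of NN intervals (ms).
#' @param scales integer scales (default 1:15).
#' @param m embedding dimension (default 2).
#' @param rFactor tolerance factor (default 0.2).
#' @return named vector \code{MSE1}, \code{MSE2}, ... (dimensionless).
#' @export
mse <- function(nn, scales = 1:15, m = 2L, rFactor = 0.2) {
  out <- rep(NA_real_, length(scales))
  names(out) <- paste0("MSE", scales)
  N <- length(nn)
  if (N < m + 2L) return(out)
  s0 <- stats::sd(nn)
  r <- rFactor * s0
  for (k in seq_along(scales)) {
    s <- scales[k]
    if (N < 10L * s) next
    if (s == 1L) {
      cg <- nn
    } else {
      nb <- floor(N / s)
      cg <- colMeans(matrix(nn[seq_len(nb * s)], nrow = s))
    }
    if (s0 == 0) { out[k] <- 0; next }
    out[k] <- sampleEntropy(cg, m, r)
  }
  out
}
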