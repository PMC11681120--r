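## Time-domain, fragmentation and Poincare HRV parameters. Each returns a
## named numeric vector; a parameter that cannot be computed from the data
## at hand is NA (never silently zero).

#' Time-domain HRV parameters
#'
#' @param nn numeric vector of NN intervals in milliseconds.
#' @return named vector: \code{AVNN} (mean, ms), \code{SDNN} (sample SD,
#'   ms), \code{RMSSD} (root mean square of successive differences, ms),
#'   \code{SEM} (\code{SDNN / sqrt(N)}, ms), \code{PNN50} (percent of
#'   successive differences strictly greater than 50 ms). With fewer than
#'   two intervals every entry is NA.
#' @examples
#' timeDomain(c(800, 900))  # RMSSD 100, PNN50 100
#' @export
timeDomain <- function(nn) {
  out <- c(AVNN = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
           SEM = NA_real_, PNN50 = NA_real_)
  n <- length(nn)
  if (n < 2L) return(out)
  d <- diff(nn)
  out["AVNN"] <- mean(nn)
  out["SDNN"] <- stats::sd(nn)
  out["SEM"] <- out["SDNN"] / sqrt(n)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["PNN50"] <- 100 * mean(abs(d) > 50)
  out
}

#' Heart-rate fragmentation indices
#'
#' Computed from the sign series of successive NN-interval differences.
#' Zero differences break segments and are never inflections. Conventions
#' (fixed and documented):
#' \itemize{
#'   \item \code{PIP}: 100 x (sign-change boundaries between consecutive
#'     nonzero-sign differences) / (number of such boundaries, i.e.
#'     differences minus one).
#'   \item \code{IALS}: inverse of the mean length (in differences) of the
#'     maximal same-sign acceleration/deceleration segments; NA when there
#'     is no segment.
#'   \item \code{PSS}: 100 x (distinct NN intervals touched by
#'     acceleration/deceleration segments spanning fewer than 3 intervals)
#'     / (total NN intervals).
#'   \item \code{PAS}: 100 x (distinct NN intervals touched by alternation
#'     segments spanning at least 4 intervals) / (total NN intervals). An
#'     alternation segment is a maximal run of consecutive differences with
#'     strictly alternating nonzero signs.
#' }
#'
#' @param nn numeric vector of NN intervals in milliseconds (>= 5).
#' @return named vector \code{PIP}, \code{IALS}, \code{PSS}, \code{PAS}
#'   (all percent except IALS, 1/beat).
#' @export
fragmentation <- function(nn) {
  out <- c(PIP = NA_real_, IALS = NA_real_, PSS = NA_real_, PAS = NA_real_)
  N <- length(nn)
  if (N < 5L) return(out)
  d <- diff(nn)
  s <- sign(d)
  M <- length(d)

  ## PIP: fraction of adjacent-difference boundaries that are sign changes
  prevS <- s[-M]; nextS <- s[-1]
  changes <- prevS != 0 & nextS != 0 & prevS != nextS
  out["PIP"] <- 100 * sum(changes) / (M - 1L)

  ## same-sign (acceleration/deceleration) segments as runs in s
  r <- rle(s)
  segLen <- r$lengths[r$values != 0]
  if (length(segLen)) out["IALS"] <- 1 / mean(segLen)

  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  short <- logical(N)
  for (j in which(r$values != 0)) {
    nInt <- r$lengths[j] + 1L  # a run of k differences spans k+1 intervals
    if (nInt < 3L) short[starts[j]:(ends[j] + 1L)] <- TRUE
  }
  out["PSS"] <- 100 * sum(short) / N

  ## alternation segments: maximal runs of alternating nonzero signs
  altIn <- logical(N)
  i <- 1L
  while (i <= M) {
    if (s[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < M && s[j + 1L] != 0 && s[j + 1L] == -s[j]) j <- j + 1L
    nInt <- (j - i + 1L) + 1L
    if (nInt >= 4L) altIn[i:(j + 1L)] <- TRUE
    i <- j + 1L
  }
  out["PAS"] <- 100 * sum(altIn) / N
  if (all(s == 0)) out[c("PSS", "PAS")] <- 0
  out
}

#' Poincare plot dispersions SD1 and SD2
#'
#' Moment conventions are fixed so that the identity
#' \code{SD1 == RMSSD / sqrt(2)} holds exactly: SD1 is the root mean square
#' of successive differences divided by \code{sqrt(2)} (second moment about
#' zero), and SD2 is the population standard deviation of successive sums
#' divided by \code{sqrt(2)}.
#'
#' @param nn numeric vector of NN intervals in milliseconds (>= 3).
#' @return named vector \code{SD1}, \code{SD2} in ms.
#' @export
poincare <- function(nn) {
  out <- c(SD1 = NA_real_, SD2 = NA_real_)
  if (length(nn) < 3L) return(out)
  d <- diff(nn)
  s <- nn[-length(nn)] + nn[-1]
  out["SD1"] <- sqrt(mean(d^2) / 2)
  out["SD2"] <- sqrt(mean((s - mean(s))^2) / 2)
  out
}
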