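## One-sample TOST equivalence testing with Cohen's-d margins, the
## significance-marker rule, and whole-table comparison.

#' One-sample TOST equivalence test with a Cohen's-d margin
#'
#' Tests whether the mean of paired differences is negligibly far from
#' zero. The equivalence bounds are \code{+/- effectSizeD * sd(diffs)}
#' (sample SD of the differences) unless explicit \code{bounds} are given.
#' Two one-sided t tests with \code{n - 1} degrees of freedom are run:
#' \code{pLower} rejects "mean below the lower bound", \code{pUpper}
#' rejects "mean above the upper bound"; equivalence is declared when both
#' are rejected, and the marker follows \code{\link{classifyMarker}}.
#'
#' @param diffs numeric vector of paired differences; non-finite values are
#'   removed (and counted in the result).
#' @param effectSizeD Cohen's d defining the margin (default 0.5).
#' @param bounds optional explicit \code{c(lower, upper)} margin overriding
#'   the d-based one.
#' @return list with \code{pLower}, \code{pUpper}, \code{marker},
#'   \code{equivalent}, \code{n}, \code{meanDiff}, \code{sdDiff},
#'   \code{deltaLower}, \code{deltaUpper}, \code{nRemoved}.
#' @examples
#' set.seed(1)
#' tostOneSample(rnorm(150), effectSizeD = 0.5)
#' @export
tostOneSample <- function(diffs, effectSizeD = 0.5, bounds = NULL) {
  nRemoved <- sum(!is.finite(diffs))
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3L) stop("need at least 3 finite differences")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (is.null(bounds)) {
    if (s == 0) stop("degenerate sample: zero-variance differences make the d-based margin undefined")
    bounds <- c(-1, 1) * effectSizeD * s
  }
  if (bounds[2] <= bounds[1]) stop("upper bound must exceed lower bound")
  if (s == 0) stop("degenerate sample: zero-variance differences")
  se <- s / sqrt(n)
  tLower <- (m - bounds[1]) / se
  tUpper <- (m - bounds[2]) / se
  pLower <- stats::pt(tLower, df = n - 1, lower.tail = FALSE)
  pUpper <- stats::pt(tUpper, df = n - 1, lower.tail = TRUE)
  marker <- classifyMarker(pLower, pUpper)
  list(pLower = pLower, pUpper = pUpper, marker = marker,
       equivalent = marker != "-", n = n, meanDiff = m, sdDiff = s,
       deltaLower = bounds[1], deltaUpper = bounds[2], nRemoved = nRemoved)
}

#' Significance marker for a TOST p-value pair
#'
#' Classification rule: \code{"-"} when at least one p-value is 0.05 or
#' larger; otherwise \code{"*"} when both are at least 0.01, \code{"**"}
#' when exactly one is below 0.01, and \code{"***"} when both are below
#' 0.01. "Below" is strict; a p-value exactly at a boundary counts as
#' above it.
#'
#' @param pLower,pUpper p-values in [0, 1].
#' @return one of \code{"-"}, \code{"*"}, \code{"**"}, \code{"***"}.
#' @examples
#' classifyMarker(0.03, 0.04)    # "*"
#' classifyMarker(0.005, 0.03)   # "**"
#' classifyMarker(0.005, 0.001)  # "***"
#' @export
classifyMarker <- function(pLower, pUpper) {
  stopifnot(pLower >= 0, pLower <= 1, pUpper >= 0, pUpper <= 1)
  if (pLower >= 0.05 || pUpper >= 0.05) return("-")
  nBelow01 <- (pLower < 0.01) + (pUpper < 0.01)
  c("*", "**", "***")[nBelow01 + 1L]
}

#' Compare two HRV feature tables by one-sample TOST
#'
#' Pairs windows across the two matrices by start time (nearest neighbour
#' within half a window length, one-to-one; unpaired windows are dropped),
#' forms per-parameter paired differences (A minus B), and runs
#' \code{\link{tostOneSample}} per parameter. Parameters not computable in
#' either matrix, or with zero-variance differences, are flagged in the
#' \code{note} column and get an NA marker; the percent-similar denominator
#' stays at the full parameter count. No multiple-testing correction is
#' applied across parameters (noted in the report).
#'
#' @param matrixA,matrixB \linkS4class{HRVWindowMatrix} objects sharing
#'   feature names.
#' @param effectSizeD Cohen's d margin (default 0.5).
#' @return an \linkS4class{EquivalenceReport}.
#' @export
compareFeatureTables <- function(matrixA, matrixB, effectSizeD = 0.5) {
  stopifnot(is(matrixA, "HRVWindowMatrix"), is(matrixB, "HRVWindowMatrix"))
  fa <- featureMatrix(matrixA); fb <- featureMatrix(matrixB)
  if (!identical(rownames(fa), rownames(fb)))
    stop("feature matrices must share feature names (same order)")
  pr <- pairWindowsByStart(windowStarts(matrixA), windowStarts(matrixB),
                           halfWindow = medianWindowLength(matrixA) / 2)
  if (!nrow(pr)) stop("zero paired windows between the two matrices")

  params <- rownames(fa)
  res <- data.frame(parameter = params, n = NA_integer_,
                    meanDiff = NA_real_, sdDiff = NA_real_,
                    pLower = NA_real_, pUpper = NA_real_,
                    marker = NA_character_, equivalent = NA,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(params)) {
    d <- fa[i, pr$a] - fb[i, pr$b]
    d <- d[is.finite(d)]
    if (length(d) < 3L) {
      res$note[i] <- "not computable (too few finite paired values)"
      next
    }
    if (stats::sd(d) == 0) {
      res$note[i] <- "degenerate (zero-variance differences)"
      next
    }
    tt <- tostOneSample(d, effectSizeD)
    res$n[i] <- tt$n; res$meanDiff[i] <- tt$meanDiff; res$sdDiff[i] <- tt$sdDiff
    res$pLower[i] <- tt$pLower; res$pUpper[i] <- tt$pUpper
    res$marker[i] <- tt$marker; res$equivalent[i] <- tt$equivalent
  }
  attr(res, "multipleTesting") <- "none (per-parameter tests are uncorrected)"
  new("EquivalenceReport", results = res, effectSize = effectSizeD,
      nPairs = nrow(pr))
}

## one-to-one nearest-first pairing of window start times
pairWindowsByStart <- function(startsA, startsB, halfWindow) {
  if (!length(startsA) || !length(startsB))
    return(data.frame(a = integer(), b = integer()))
  d <- abs(outer(startsA, startsB, "-"))
  cand <- which(d <= halfWindow, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(a = integer(), b = integer()))
  cand <- cand[order(d[cand]), , drop = FALSE]
  usedA <- logical(length(startsA)); usedB <- logical(length(startsB))
  a <- integer(); b <- integer()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      a <- c(a, i); b <- c(b, j)
    }
  }
  o <- order(a)
  data.frame(a = a[o], b = b[o])
}

medianWindowLength <- function(m) {
  len <- windowEnds(m) - windowStarts(m)
  if (!length(len)) return(Inf)
  stats::median(len)
}

#' Percent-similar summary from a printed marker column
#'
#' Applies the marker rule in reverse: an entry is "similar" iff it carries
#' at least one asterisk. The denominator is the full row count (39 for the
#' canonical parameter set) regardless of NA entries.
#'
#' @param markers character vector of markers
#'   (\code{"-"}, \code{"*"}, \code{"**"}, \code{"***"}).
#' @return percent similar (0-100).
#' @examples
#' percentSimilarFromMarkers(c("***", "-", "*"))  # 66.7
#' @export
percentSimilarFromMarkers <- function(markers) {
  stopifnot(all(markers %in% c("-", "*", "**", "***")))
  100 * sum(markers != "-") / length(markers)
}
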