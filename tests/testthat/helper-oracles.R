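# Independent naive-definition oracles. These deliberately use plain loops
# and a separate code path from the package implementation.

oracleTimeDomain <- function(nn) {
  n <- length(nn)
  avnn <- sum(nn) / n
  sdnn <- sqrt(sum((nn - avnn)^2) / (n - 1))
  d <- nn[-1] - nn[-n]
  c(AVNN = avnn, SDNN = sdnn, RMSSD = sqrt(sum(d^2) / length(d)),
    SEM = sdnn / sqrt(n), PNN50 = 100 * sum(abs(d) > 50) / length(d))
}

# exhaustive segment enumeration for the fragmentation indices
oracleFragmentation <- function(nn) {
  N <- length(nn)
  d <- nn[-1] - nn[-N]
  s <- sign(d)
  M <- length(d)
  infl <- 0
  for (i in 2:M) if (s[i] != 0 && s[i - 1] != 0 && s[i] != s[i - 1])
    infl <- infl + 1
  pip <- 100 * infl / (M - 1)

  # same-sign runs
  segs <- list()
  i <- 1
  while (i <= M) {
    if (s[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < M && s[j + 1] == s[i]) j <- j + 1
    segs[[length(segs) + 1]] <- c(i, j)
    i <- j + 1
  }
  ials <- if (length(segs)) 1 / mean(vapply(segs, function(g) g[2] - g[1] + 1,
                                            numeric(1))) else NA_real_
  shortInt <- rep(FALSE, N)
  for (g in segs) if ((g[2] - g[1] + 2) < 3) shortInt[g[1]:(g[2] + 1)] <- TRUE
  pss <- 100 * sum(shortInt) / N

  # alternation runs
  altInt <- rep(FALSE, N)
  i <- 1
  while (i <= M) {
    if (s[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < M && s[j + 1] != 0 && s[j + 1] == -s[j]) j <- j + 1
    if ((j - i + 2) >= 4) altInt[i:(j + 1)] <- TRUE
    i <- j + 1
  }
  pas <- 100 * sum(altInt) / N
  if (all(s == 0)) { pss <- 0; pas <- 0 }
  c(PIP = pip, IALS = ials, PSS = pss, PAS = pas)
}

oraclePoincare <- function(nn) {
  n <- length(nn)
  d <- nn[-1] - nn[-n]
  su <- nn[-1] + nn[-n]
  c(SD1 = sqrt(sum(d^2) / length(d) / 2),
    SD2 = sqrt(sum((su - mean(su))^2) / length(su) / 2))
}

# classic Lomb formula, scalar loop
oracleLombDensity <- function(times, values, freqs) {
  y <- values - mean(values)
  dtMean <- mean(diff(times))
  out <- numeric(length(freqs))
  for (q in seq_along(freqs)) {
    w <- 2 * pi * freqs[q]
    num <- 0; den <- 0
    for (t in times) { num <- num + sin(2 * w * t); den <- den + cos(2 * w * t) }
    tau <- atan2(num, den) / (2 * w)
    c1 <- 0; c2 <- 0; s1 <- 0; s2 <- 0
    for (i in seq_along(times)) {
      a <- w * (times[i] - tau)
      c1 <- c1 + y[i] * cos(a); c2 <- c2 + cos(a)^2
      s1 <- s1 + y[i] * sin(a); s2 <- s2 + sin(a)^2
    }
    out[q] <- 2 * dtMean * 0.5 * (c1^2 / c2 + s1^2 / s2)
  }
  out
}

# O(N^2) template-matching sample entropy
oracleSampEn <- function(x, m, r) {
  N <- length(x)
  A <- 0; B <- 0
  for (i in 1:(N - m - 1)) {
    for (j in (i + 1):(N - m)) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# naive DFA via lm() per box
oracleDFASlope <- function(nn, boxSizes) {
  N <- length(nn)
  boxSizes <- boxSizes[floor(N / boxSizes) >= 2]
  y <- cumsum(nn - mean(nn))
  Fn <- sapply(boxSizes, function(b) {
    nb <- floor(N / b)
    res <- c()
    for (k in 1:nb) {
      seg <- y[((k - 1) * b + 1):(k * b)]
      fit <- lm(seg ~ seq_len(b))
      res <- c(res, residuals(fit))
    }
    sqrt(mean(res^2))
  })
  unname(coef(lm(log(Fn) ~ log(boxSizes)))[2])
}

# footnote marker rule written as a lookup over explicit cases
oracleMarker <- function(pl, pu) {
  below05 <- function(p) p < 0.05
  below01 <- function(p) p < 0.01
  if (!below05(pl) || !below05(pu)) return("-")
  if (below01(pl) && below01(pu)) return("***")
  if (below01(pl) || below01(pu)) return("**")
  "*"
}
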