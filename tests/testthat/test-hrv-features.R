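test_that("time-domain parameters match their definitions", {
  expect_equal(timeDomain(c(1000, 1000, 1000)),
               c(AVNN = 1000, SDNN = 0, RMSSD = 0, SEM = 0, PNN50 = 0))
  td <- timeDomain(c(800, 900))
  expect_equal(td[["RMSSD"]], 100)
  expect_equal(td[["PNN50"]], 100)
  expect_true(all(is.na(timeDomain(c(800)))))

  set.seed(21)
  nn <- runif(500, 700, 1100)
  expect_equal(timeDomain(nn), oracleTimeDomain(nn), tolerance = 1e-12)
})

test_that("fragmentation indices match the exhaustive segment oracle", {
  # monotone run: no inflection, no short or alternation segments
  up <- seq(800, 900, by = 10)
  fr <- fragmentation(up)
  expect_equal(unname(fr[c("PIP", "PSS", "PAS")]), c(0, 0, 0))
  # perfect alternation: every boundary an inflection, one alternation
  # segment covering all intervals
  alt <- rep(c(800, 900), length.out = 7)
  fa <- fragmentation(alt)
  expect_equal(fa[["PIP"]], 100)
  expect_equal(fa[["PAS"]], 100)

  # random +/-1 walks agree with the brute-force enumeration exactly
  set.seed(22)
  for (rep in 1:10) {
    nn <- 900 + cumsum(sample(c(-1, 1), 200, replace = TRUE))
    expect_identical(fragmentation(nn), oracleFragmentation(nn))
  }
  # zero differences break segments
  nn0 <- c(800, 800, 810, 820, 810, 810, 800, 790, 800)
  expect_identical(fragmentation(nn0), oracleFragmentation(nn0))
  expect_true(all(is.na(fragmentation(c(800, 810, 820)))))
})

test_that("Poincare dispersions obey the fixed moment conventions", {
  expect_equal(poincare(rep(900, 10)), c(SD1 = 0, SD2 = 0))
  # closed form on the alternating series
  alt <- rep(c(800, 900), 10)
  pc <- poincare(alt)
  expect_equal(pc[["SD1"]], 50 * sqrt(2), tolerance = 1e-12)
  expect_lt(pc[["SD2"]], 1e-9)
  # SD1 = RMSSD / sqrt(2) identity on random windows
  set.seed(23)
  for (rep in 1:20) {
    nn <- runif(50, 700, 1100)
    expect_equal(poincare(nn)[["SD1"]],
                 timeDomain(nn)[["RMSSD"]] / sqrt(2), tolerance = 1e-12)
    expect_equal(poincare(nn), oraclePoincare(nn), tolerance = 1e-12)
  }
})

test_that("Lomb periodogram matches the naive per-frequency formula", {
  set.seed(24)
  times <- cumsum(runif(80, 0.7, 1.1))
  vals <- rnorm(80, 900, 40)
  freqs <- seq(0.02, 0.4, by = 0.01)
  mine <- lombPeriodogram(times, vals, freqs)$density
  expect_equal(mine, oracleLombDensity(times, vals, freqs), tolerance = 1e-9)
})

test_that("frequency-domain parameters recover planted modulation and handle degenerate input", {
  # HF-only modulation: HF peak at 0.25 Hz, HF norm >= 95
  bHF <- simulateRR(simulationConfig(duration = 320, lfAmp = 0, hfAmp = 30,
                                     noiseSd = 0, seed = 25))
  w <- segmentWindows(bHF, hrvWindowConfig(300, "time_overlap", overlap = 0))
  fd <- frequencyDomain(w[[1]])
  expect_lt(abs(fd[["HF_PEAK"]] - 0.25), 0.01)
  expect_gte(fd[["HF_NORM"]], 95)

  # LF-only modulation: LF peak at 0.1 Hz
  bLF <- simulateRR(simulationConfig(duration = 320, lfAmp = 40, hfAmp = 0,
                                     noiseSd = 0, seed = 26))
  wl <- segmentWindows(bLF, hrvWindowConfig(300, "time_overlap", overlap = 0))
  fdl <- frequencyDomain(wl[[1]])
  expect_lt(abs(fdl[["LF_PEAK"]] - 0.1), 0.01)

  # constant series: powers ~ 0, peaks not computable
  fc <- frequencyDomain(BeatSeries(seq(0, 300, by = 0.9)))
  expect_lte(max(fc[c("VLF_POWER", "LF_POWER", "HF_POWER")]), 1e-6)
  expect_true(all(is.na(fc[c("LF_PEAK", "HF_PEAK")])))

  # norms against LF + HF sum to 100 exactly
  set.seed(27)
  b <- simulateRR(simulationConfig(duration = 400, seed = 27))
  fb <- frequencyDomain(segmentWindows(b, hrvWindowConfig(300, "time_overlap",
                                                          overlap = 0))[[1]])
  expect_equal(fb[["LF_NORM"]] + fb[["HF_NORM"]], 100, tolerance = 1e-9)
})

test_that("DFA slopes hit the theoretical exponents and match the naive oracle", {
  set.seed(28)
  nn <- rnorm(300, 900, 30)
  expect_equal(dfa(nn)[["ALPHA1"]], oracleDFASlope(nn, 4:15), tolerance = 1e-9)
  expect_equal(dfa(nn)[["ALPHA2"]], oracleDFASlope(nn, 16:64), tolerance = 1e-9)
  # degenerate: constant series has zero fluctuations at all scales
  expect_true(all(is.na(dfa(rep(900, 200)))))
  # too short for the large-box band
  expect_true(is.na(dfa(rnorm(40, 900, 30))[["ALPHA2"]]))
})

test_that("sample entropy matches both the O(N^2) oracle and pracma", {
  set.seed(29)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  expect_equal(sampleEntropy(x, 2, r), oracleSampEn(x, 2, r), tolerance = 1e-12)
  skip_if_not_installed("pracma")
  expect_equal(sampleEntropy(x, 2, r),
               pracma::sample_entropy(x, edim = 2, r = r), tolerance = 1e-12)
})

test_that("multiscale entropy: constant series, short-series flags, oracle equality", {
  cons <- mse(rep(900, 200))
  computable <- paste0("MSE", 1:15)[200 >= 10 * (1:15)]
  expect_true(all(cons[computable] == 0))
  expect_true(all(is.na(cons[setdiff(names(cons), computable)])))

  set.seed(30)
  nn <- rnorm(300, 900, 30)
  m <- mse(nn)
  r <- 0.2 * sd(nn)
  expect_equal(m[["MSE1"]], oracleSampEn(nn, 2, r), tolerance = 1e-12)
  cg3 <- colMeans(matrix(nn[1:(100 * 3)], nrow = 3))
  expect_equal(m[["MSE3"]], oracleSampEn(cg3, 2, r), tolerance = 1e-12)
  # a 100-interval window cannot support scales above 10
  short <- mse(rnorm(100, 900, 30))
  expect_true(all(is.na(short[paste0("MSE", 11:15)])))
})

test_that("white-noise MSE decreases with scale (coarse-graining property)", {
  ok <- logical(50)
  for (i in seq_along(ok)) {
    set.seed(400 + i)
    m <- mse(rnorm(3000, 900, 30))
    rho <- cor(1:15, m, method = "spearman")
    ok[i] <- rho < 0
  }
  expect_gte(mean(ok), 0.95)
})

test_that("extractHRV fills a 39-row matrix and gates long-term parameters", {
  b <- simulateRR(simulationConfig(duration = 1200, seed = 31))
  m <- extractHRV(b, hrvWindowConfig(60, "time_overlap", overlap = 30))
  expect_s4_class(m, "HRVWindowMatrix")
  expect_equal(rownames(featureMatrix(m)), hrvFeatureNames())
  expect_equal(ncol(m), 38)  # (1200 - 60) / 30 + 1
  td <- featureMatrix(m)[c("AVNN", "SDNN", "RMSSD", "SEM", "PNN50"), ]
  expect_false(anyNA(td))
  # short windows flag every long-term parameter not-computable
  expect_true(all(is.na(featureMatrix(m)[longTermFeatures(), ])))

  m5 <- extractHRV(b, hrvWindowConfig(300, "time_overlap", overlap = 0))
  expect_false(anyNA(featureMatrix(m5)["VLF_POWER", ]))

  expect_warning(e <- extractHRV(BeatSeries(numeric()), hrvWindowConfig(60)),
                 "shorter")
  expect_equal(ncol(e), 0)
})

test_that("every feature is invariant to a time-origin shift", {
  b <- simulateRR(simulationConfig(duration = 400, seed = 32))
  cfg <- hrvWindowConfig(300, "time_overlap", overlap = 0)
  m1 <- featureMatrix(extractHRV(b, cfg))
  b2 <- BeatSeries(beatTimes(b) + 1234.5)
  m2 <- featureMatrix(extractHRV(b2, cfg))
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("AVNN of simulated sessions recovers the configured mean RR", {
  b0 <- simulateRR(simulationConfig(duration = 300, noiseSd = 0, lfAmp = 0,
                                    hfAmp = 0, seed = 33))
  expect_equal(mean(nnIntervals(b0)), 900, tolerance = 1e-6)
  b1 <- simulateRR(simulationConfig(duration = 300, seed = 34))
  expect_lt(abs(mean(nnIntervals(b1)) - 900) / 900, 0.01)
})
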