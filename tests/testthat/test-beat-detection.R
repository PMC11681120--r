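test_that("AMPD recovers sine peaks, impulses, and rejects monotone signals", {
  # 10 full cycles at 50 samples/cycle: every analytic maximum recovered
  # within one sample
  fs <- 50
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  peaks <- detectPeaksAMPD(RawSignal(sin(2 * pi * t), fs))
  expect_length(peaks, 10)
  analytic <- 0.25 + 0:9
  expect_true(all(abs((peaks - 1) / fs - analytic) <= 1 / fs))
  # brute-force local-maximum oracle agrees on the noise-free signal
  # (>= on one side: a crest can fall exactly between two equal samples)
  x <- sin(2 * pi * t)
  bruteMax <- which(vapply(2:(length(x) - 1), function(i)
    x[i] >= x[i - 1] && x[i] >= x[i + 1] &&
      (x[i] > x[i - 1] || x[i] > x[i + 1]), logical(1))) + 1L
  expect_true(all(vapply(peaks, function(p) min(abs(bruteMax - p)) <= 1,
                         logical(1))))

  # single impulse in a zero baseline
  z <- numeric(301); z[101] <- 1
  expect_identical(detectPeaksAMPD(RawSignal(z, fs)), 101L)

  # strictly increasing ramp: constant after detrending, no peaks
  expect_length(detectPeaksAMPD(RawSignal(seq_len(300) * 0.1, fs)), 0)

  expect_error(detectPeaksAMPD(RawSignal(sin(t), fs), maxScale = 0),
               "maxScale")
})

test_that("energy QRS detector finds spikes, honours refractory, rejects bad input", {
  fs <- 200
  beats <- BeatSeries(1:120)  # 1 Hz spike train
  sig <- simulateWaveform(beats, "ecg", fs = fs)
  peaks <- detectRPeaksEnergy(sig)
  expect_length(peaks, 120)
  expect_true(max(abs((peaks - 1) / fs - beatTimes(beats))) <= 0.02)

  # zero signal -> no peaks (need >= 2 s of samples)
  expect_length(detectRPeaksEnergy(RawSignal(numeric(1000), fs)), 0)

  # two spikes 100 ms apart with a 250-ms refractory collapse to one
  t <- seq(0, 3, by = 1 / fs)
  x <- exp(-((t - 1.0)^2) / (2 * 0.008^2)) + exp(-((t - 1.1)^2) / (2 * 0.008^2))
  p2 <- detectRPeaksEnergy(RawSignal(x, fs, modality = "ecg"),
                           refractory = 0.25)
  expect_length(p2, 1)

  expect_error(detectRPeaksEnergy(sig, band = c(25, 5)), "band")
  expect_error(detectRPeaksEnergy(RawSignal(rnorm(100), fs)), "2 s")
})

test_that("agreement fusion is one-to-one, nearest-first, and a subset of primary", {
  # identical lists pass through
  expect_identical(fuseDetections(c(10L, 50L, 90L), c(10L, 50L, 90L),
                                  0.15, 200), c(10L, 50L, 90L))
  # disjoint lists beyond tolerance -> empty
  expect_length(fuseDetections(c(10L, 50L), c(200L, 400L), 0.05, 200), 0)
  # brute-force matching on the worked example (tolerance 5 samples)
  expect_identical(fuseDetections(c(100L, 300L, 500L), c(102L, 501L),
                                  tolerance = 5 / 200, samplingRate = 200),
                   c(100L, 500L))
  expect_error(fuseDetections(1:3, 1:3, tolerance = 0, samplingRate = 200),
               "tolerance")

  # property: subset of primary, never longer than either input
  set.seed(11)
  for (rep in 1:20) {
    p <- sort(sample(1000, 30))
    s <- sort(sample(1000, 25))
    f <- fuseDetections(p, s, 0.05, 200)
    expect_true(all(f %in% p))
    expect_lte(length(f), min(length(p), length(s)))
  }
})

test_that("peak-to-interval conversion is exact arithmetic", {
  b <- peaksToIntervals(c(1, 201, 401), 200)
  expect_equal(nnIntervals(b), c(1000, 1000))
  expect_equal(nnIntervals(peaksToIntervals(c(1, 151), 300)), 500)
  b3 <- peaksToIntervals(seq(1, by = 180, length.out = 601), 200)
  expect_length(nnIntervals(b3), 600)
  expect_true(all(abs(nnIntervals(b3) - 900) <= 1e-9 * 900))
  # exact round trip for integer indices
  idx <- sort(sample(100000, 500))
  bt <- beatTimes(peaksToIntervals(idx, 128))
  expect_equal(bt, (idx - 1) / 128, tolerance = 1e-12)
  expect_error(peaksToIntervals(5L, 200), "at least 2")
  expect_error(peaksToIntervals(c(5L, 5L), 200), "strictly increasing")
})

test_that("noise-free pulse round trip recovers every beat; mild noise barely changes the fused count", {
  beats <- simulateRR(simulationConfig(duration = 120, noiseSd = 0, seed = 3))
  sig <- simulateWaveform(beats, "pulse", fs = 100)
  peaks <- detectPeaksAMPD(sig)
  pt <- (peaks - 1) / 100
  hits <- vapply(beatTimes(beats), function(b) any(abs(pt - b) <= 0.02),
                 logical(1))
  expect_gte(mean(hits), 0.99)
  expect_lte(length(peaks), length(beats))  # no spurious peaks

  # SNR 20 dB on an ECG-like record: fused count within 1%
  ecg <- simulateWaveform(beats, "ecg", fs = 200)
  ecgN <- simulateWaveform(beats, "ecg", fs = 200, snrDb = 20, seed = 4)
  fuse <- function(s) fuseDetections(detectRPeaksEnergy(s),
                                     detectPeaksAMPD(s), 0.15, 200)
  n0 <- length(fuse(ecg)); n1 <- length(fuse(ecgN))
  expect_lte(abs(n1 - n0) / n0, 0.01)
})
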