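# Shared fixture builders (all generated in code, seeded).

# full synthetic session -> calibrated labelled active windows
makeParticipantWindows <- function(seed, planted = TRUE) {
  sc <- sessionConfig(seed = seed,
                      lieRRDrop = if (planted) 0.05 else 0,
                      lieHFReduction = if (planted) 0.4 else 0)
  ses <- simulateSession(sc, simulationConfig(seed = seed + 1000))
  bt <- beatTimes(ses$beats)
  baseline <- BeatSeries(bt[bt < ses$baselineSpan[2]])
  blm <- suppressMessages(
    extractHRV(baseline, hrvWindowConfig(30, "beat_step", stepBeats = 2)))
  stats <- computeBaselineStats(blm)
  suppressWarnings(labelActiveWindows(ses$beats, ses$schedule, stats))
}

makeCohortWindows <- function(n, seed0, planted = TRUE) {
  lapply(seq_len(n), function(i) makeParticipantWindows(seed0 + i, planted))
}

# feature matrix of iid normals with fixed geometry
randomFeatureMatrix <- function(nWindows, seed, mean = 0, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(39 * nWindows, mean, sd), nrow = 39,
              dimnames = list(hrvFeatureNames(), NULL))
  starts <- seq(0, by = 30, length.out = nWindows)
  HRVWindowMatrix(m, starts, starts + 60)
}
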