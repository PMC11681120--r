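test_that("baseline statistics use the sample convention and flag degenerates", {
  m <- matrix(c(4, 6), nrow = 1, ncol = 2,
              dimnames = list("AVNN", NULL))
  # too few windows
  expect_error(computeBaselineStats(m), "insufficient")
  m10 <- matrix(rep(c(4, 6), 5), nrow = 1, dimnames = list("AVNN", NULL))
  st <- computeBaselineStats(m10)
  expect_equal(unname(st$mu), 5)
  expect_equal(unname(st$sigma), sd(rep(c(4, 6), 5)))
  # identical windows: all sigma zero, everything unusable
  flat <- matrix(7, nrow = 3, ncol = 12,
                 dimnames = list(c("AVNN", "SDNN", "RMSSD"), NULL))
  stFlat <- computeBaselineStats(flat)
  expect_true(all(stFlat$sigma == 0))
  expect_false(any(stFlat$usable))
})

test_that("calibration is the exact baseline z-score and affine invariant", {
  st <- list(mu = c(AVNN = 5, SDNN = 1.5), sigma = c(AVNN = 1.5, SDNN = 2),
             usable = c(AVNN = TRUE, SDNN = TRUE))
  expect_equal(calibrate(c(AVNN = 5, SDNN = 1.5), st),
               c(AVNN = 0, SDNN = 0))
  expect_equal(calibrate(c(AVNN = 6.5, SDNN = 3.5), st),
               c(AVNN = 1, SDNN = 1))
  expect_equal(calibrate(c(AVNN = 2), st)[["AVNN"]], -2)
  # affine transform of the raw feature + recomputed stats leaves the
  # calibrated value unchanged
  set.seed(51)
  raw <- matrix(rnorm(39 * 20, 10, 2), nrow = 39,
                dimnames = list(hrvFeatureNames(), NULL))
  s1 <- computeBaselineStats(raw)
  x <- raw[, 1]
  a <- 3.7; b <- -12
  s2 <- computeBaselineStats(raw * a + b)
  expect_equal(calibrate(x, s1), calibrate(x * a + b, s2), tolerance = 1e-9)
})

test_that("active-state windows inherit question labels with the y convention", {
  b <- BeatSeries(0:400)
  blm <- suppressMessages(extractHRV(BeatSeries(0:300),
                                     hrvWindowConfig(30, "beat_step",
                                                     stepBeats = 2)))
  st <- computeBaselineStats(blm)
  sched <- data.frame(question_id = c("Q1", "Q2"),
                      start_s = c(310, 375), end_s = c(370.5, 395),
                      label = c("lie", "truth"), y = c(0, 1),
                      stringsAsFactors = FALSE)
  expect_warning(act <- labelActiveWindows(b, sched, st), "Q2")
  # Q1: 60-s span, 1-s beats -> 16 windows, all labelled lie (y = 0)
  expect_equal(ncol(act), 16)
  expect_true(all(windowLabels(act) == 0))
  # no questions -> empty result
  none <- labelActiveWindows(b, sched[0, ], st)
  expect_equal(ncol(none), 0)
})

test_that("per-participant class means equal brute-force label averaging", {
  m <- matrix(c(1, 3, 2), nrow = 1, dimnames = list("AVNN", NULL))
  pm <- participantMeans(m, y = c(0, 0, 1))
  expect_equal(unname(pm$ML), 2)
  expect_equal(unname(pm$MT), 2)
  expect_equal(pm$NL, 2)

  set.seed(52)
  mm <- matrix(rnorm(39 * 100), nrow = 39,
               dimnames = list(hrvFeatureNames(), NULL))
  y <- rbinom(100, 1, 0.5)
  pm2 <- participantMeans(mm, y = y)
  expect_equal(pm2$ML, apply(mm[, y == 0], 1, mean), tolerance = 1e-12)
  expect_equal(pm2$MT, apply(mm[, y == 1], 1, mean), tolerance = 1e-12)
  expect_error(participantMeans(mm, y = rep(1, 100)), "at least one")
})

test_that("sign-split groups follow the same/opposite-sign rule with zero as same", {
  mk <- function(ml, mt) list(ML = c(F1 = ml), MT = c(F1 = mt))
  sums <- list(mk(-0.2, 0.5), mk(0.1, 0.5), mk(1, 0))
  g <- splitGroups(sums, "F1")
  expect_equal(g$neg, 1L)         # opposite signs
  expect_equal(g$pos, c(2L, 3L))  # same sign; zero counts as same
})

test_that("the scoring function matches hand evaluation and its limit behaviour", {
  sc <- scoreFeature(c(1, 2, 3), c(2, 4), beta = 0.45)
  expect_equal(sc$S, 0.45 * 2 + 0.55 * 3 / sqrt(2), tolerance = 1e-9)
  # empty negative group: only the positive term remains
  expect_equal(scoreFeature(c(1, 2, 3), numeric(), 0.45)$S, 0.45 * 2)
  # beta limits
  expect_equal(scoreFeature(c(1, 2, 3), c(2, 4), beta = 1)$S, 2)
  expect_equal(scoreFeature(c(1, 2, 3), c(2, 4), beta = 0)$S, 3 / sqrt(2))
  # zero-SD group with nonzero mean: that term is dropped, not the feature
  inf1 <- scoreFeature(c(2, 2), c(2, 4), 0.45)
  expect_equal(inf1$S, 0.55 * 3 / sqrt(2))
  expect_false(inf1$degenerate)
  # no informative term at all
  expect_true(scoreFeature(c(2, 2), numeric(), 0.45)$degenerate)
  # invariant to swapping enumeration order within groups
  expect_equal(scoreFeature(c(3, 1, 2), c(4, 2), 0.45)$S, sc$S)
})

test_that("feature selection recovers planted features and breaks ties canonically", {
  planted <- c("PNN50", "PAS", "HF_PEAK")
  hits <- logical(20)
  for (i in seq_along(hits)) {
    coh <- simulateCalibratedCohort(seed = 700 + i, planted = planted)
    sel <- selectFeatures(coh)
    hits[i] <- setequal(sel$feature, planted)
  }
  expect_gte(mean(hits), 0.95)

  # deterministic tie-break: two features with identical windows must tie
  # and resolve in canonical order (RMSSD before SD1, which is RMSSD/sqrt 2
  # after calibration)
  coh2 <- makeCohortWindows(3, 600, planted = TRUE)
  sel2 <- suppressWarnings(selectFeatures(coh2, k = 25))  # < 25 scorable
  iR <- match("RMSSD", sel2$feature); iS <- match("SD1", sel2$feature)
  expect_equal(sel2$score[iR], sel2$score[iS], tolerance = 1e-9)
  expect_lt(iR, iS)

  # k larger than the scorable set
  small <- simulateCalibratedCohort(nParticipants = 3, seed = 61,
                                    featureNames = hrvFeatureNames())
  restricted <- lapply(small, function(m) m[c("AVNN", "SDNN"), ])
  expect_warning(selTwo <- selectFeatures(restricted, k = 3,
                                          candidates = c("AVNN", "SDNN")),
                 "scorable")
  expect_equal(nrow(selTwo), 2)
})

test_that("the naive classifier is the majority rule with ties to truth", {
  expect_equal(naiveClassifier(c(1, 1, 0)),
               list(prediction = 1, accuracy = 2 / 3))
  expect_equal(naiveClassifier(c(0, 0, 0)), list(prediction = 0, accuracy = 1))
  expect_equal(naiveClassifier(c(1, 0)), list(prediction = 1, accuracy = 0.5))
})

test_that("train/evaluate: separable features give perfect accuracy; same seed reproduces", {
  set.seed(53)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(39 * n, 0, 0.1), nrow = 39,
              dimnames = list(hrvFeatureNames(), NULL))
  m["AVNN", y == 0] <- m["AVNN", y == 0] + 10  # disjoint ranges
  r1 <- trainEvaluate(m, "AVNN", y = y, seed = 99)
  expect_true(all(r1$modelAccuracy == 100))
  expect_equal(r1$better + r1$equal + r1$worse, 1)
  r2 <- trainEvaluate(m, "AVNN", y = y, seed = 99)
  expect_identical(r1, r2)
})

test_that("shuffled labels leave the model at the naive level (window-level null)", {
  accs <- sapply(1:15, function(i) {
    set.seed(800 + i)
    n <- 100
    m <- matrix(rnorm(39 * n), nrow = 39,
                dimnames = list(hrvFeatureNames(), NULL))
    y <- sample(rep(c(0, 1), each = n / 2))
    r <- trainEvaluate(m, c("AVNN", "PAS", "HF_PEAK"), y = y,
                       seed = 800 + i, nRepeats = 5)
    c(model = mean(r$modelAccuracy), naive = mean(r$naiveAccuracy))
  })
  expect_lt(abs(mean(accs["model", ]) - mean(accs["naive", ])), 5)
})

test_that("cohort aggregation arithmetic and report invariants", {
  one <- list(modelAccuracy = c(80, 90), naiveAccuracy = c(50, 60),
              better = 1, equal = 0, worse = 0)
  rep1 <- aggregateReport(list(one))
  expect_equal(rep1$modelAccuracy$mean, 85)
  expect_equal(rep1$modelAccuracy$sd, 0)
  two <- list(modelAccuracy = 90, naiveAccuracy = 55,
              better = 0.5, equal = 0.5, worse = 0)
  rep2 <- aggregateReport(list(one, two))
  expect_equal(rep2$modelAccuracy$mean, 87.5)
  expect_equal(rep2$modelAccuracy$sd, sd(c(85, 90)))
  expect_equal(rep2$betterFraction$mean + rep2$equalFraction$mean +
                 rep2$worseFraction$mean, 1)
})

test_that("the pipeline isolates feature selection from training participants", {
  coh <- simulateCalibratedCohort(nParticipants = 6, seed = 71)
  # poison the would-be training participants: if selection touched them,
  # the planted features could not come out on top
  set.seed(71)
  res <- runLiePipeline(coh, seed = 71)
  expect_true(all(res$externalIdx %in% seq_along(coh)))
  trainIdx <- setdiff(seq_along(coh), res$externalIdx)
  cohPoison <- coh
  for (i in trainIdx) {
    m <- featureMatrix(cohPoison[[i]])
    m[] <- rnorm(length(m))  # destroy any signal in the training group
    cohPoison[[i]] <- HRVWindowMatrix(m, windowStarts(cohPoison[[i]]),
                                      windowEnds(cohPoison[[i]]),
                                      y = windowLabels(cohPoison[[i]]))
  }
  resPoison <- runLiePipeline(cohPoison, seed = 71)
  expect_identical(res$selected, resPoison$selected)
})
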