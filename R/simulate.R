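## IPFM-style synthetic beat, waveform and session generators. Every
## generator is a pure function of its seed and configuration.

#' Configuration for the RR-interval generator
#'
#' The generator emulates resting autonomic structure: an instantaneous RR
#' length modulated by a low-frequency (Mayer-wave, ~0.1 Hz) and a
#' high-frequency (respiratory, ~0.25 Hz) sinusoid, plus white
#' interval-to-interval noise. Defaults describe a healthy resting adult:
#' mean RR 900 ms, LF depth 40 ms, HF depth 30 ms, noise SD 15 ms.
#'
#' @param meanRR mean RR interval in ms.
#' @param lfFreq,hfFreq modulation frequencies in Hz.
#' @param lfAmp,hfAmp modulation depths in ms.
#' @param noiseSd white interval noise SD in ms.
#' @param duration record duration in seconds.
#' @param seed integer seed.
#' @param fs sampling rate (Hz) for waveform synthesis.
#' @return list of class \code{"SimulationConfig"}. Errors if the
#'   positivity invariant \code{meanRR > 2 (lfAmp + hfAmp + 3 noiseSd)} is
#'   violated (negative intervals would become possible).
#' @export
simulationConfig <- function(meanRR = 900, lfFreq = 0.1, hfFreq = 0.25,
                             lfAmp = 40, hfAmp = 30, noiseSd = 15,
                             duration = 900, seed = 1, fs = 200) {
  if (meanRR <= 2 * (lfAmp + hfAmp + 3 * noiseSd))
    stop("invalid config: meanRR must exceed 2*(lfAmp + hfAmp + 3*noiseSd)")
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  structure(list(meanRR = meanRR, lfFreq = lfFreq, hfFreq = hfFreq,
                 lfAmp = lfAmp, hfAmp = hfAmp, noiseSd = noiseSd,
                 duration = duration, seed = as.integer(seed), fs = fs),
            class = "SimulationConfig")
}

## integrate an instantaneous rate (beats/s) on a fine grid and emit beat
## times at unit crossings of the integral (IPFM)
ipfmBeats <- function(rateFun, duration, dt = 0.01) {
  tg <- seq(0, duration, by = dt)
  rate <- rateFun(tg)
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  nBeats <- floor(cum[length(cum)])
  if (nBeats < 1L) return(numeric())
  stats::approx(cum, tg, xout = 0:nBeats, ties = "ordered")$y
}

#' Simulate an RR-interval series (IPFM model)
#'
#' Beat times are emitted where the integral of the instantaneous rate
#' \code{1000 / rr(t)} crosses successive integers, with
#' \code{rr(t) = meanRR + lfAmp sin(2 pi lfFreq t) + hfAmp sin(2 pi hfFreq
#' t)} (ms); white Gaussian noise (SD \code{noiseSd} ms) is then added to
#' each interval. With zero modulation and zero noise the intervals equal
#' \code{meanRR} exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param modulators optional list of functions of time overriding the
#'   session-level components: \code{rrFactor(t)} (multiplies the
#'   instantaneous RR) and \code{hfAmpFactor(t)} (multiplies the HF depth).
#'   Used by \code{\link{simulateSession}} to plant transient effects.
#' @return a \linkS4class{BeatSeries}.
#' @examples
#' b <- simulateRR(simulationConfig(duration = 120, seed = 7))
#' mean(nnIntervals(b))
#' @export
simulateRR <- function(config, modulators = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  rrFactor <- if (!is.null(modulators$rrFactor)) modulators$rrFactor
              else function(t) rep(1, length(t))
  hfFactor <- if (!is.null(modulators$hfAmpFactor)) modulators$hfAmpFactor
              else function(t) rep(1, length(t))
  rateFun <- function(t) {
    rr <- (config$meanRR +
             config$lfAmp * sin(2 * pi * config$lfFreq * t) +
             config$hfAmp * hfFactor(t) * sin(2 * pi * config$hfFreq * t)) *
      rrFactor(t)
    1000 / rr
  }
  bt <- ipfmBeats(rateFun, config$duration)
  if (length(bt) < 2L) stop("duration too short: fewer than 2 beats generated")
  if (config$noiseSd > 0) {
    set.seed(config$seed)
    nn <- diff(bt) * 1000 + rnorm(length(bt) - 1L, 0, config$noiseSd)
    if (any(nn <= 0)) stop("noise produced a non-positive interval")
    bt <- c(bt[1], bt[1] + cumsum(nn) / 1000)
  }
  BeatSeries(bt)
}

#' Synthesise a waveform from beat times
#'
#' Pulse-like: a smooth unimodal Gaussian pulse per beat (apex at the beat
#' time). ECG-like: a narrow biphasic spike (small negative Q and S lobes
#' around a tall R wave, R apex at the beat time). Additive white Gaussian
#' noise at the configured SNR.
#'
#' @param beats a \linkS4class{BeatSeries} (non-empty).
#' @param modality \code{"pulse"} or \code{"ecg"}.
#' @param fs sampling rate in Hz (>= 50).
#' @param snrDb signal-to-noise ratio in dB (\code{Inf} = noise-free).
#' @param pulseWidth Gaussian pulse SD in seconds (pulse modality; the
#'   effective pulse support of about 6 SD must stay below the minimum
#'   interval).
#' @param seed seed for the noise draw.
#' @return a \linkS4class{RawSignal}.
#' @export
simulateWaveform <- function(beats, modality = c("pulse", "ecg"), fs = 200,
                             snrDb = Inf, pulseWidth = 0.05, seed = 1) {
  modality <- match.arg(modality)
  stopifnot(is(beats, "BeatSeries"))
  bt <- beatTimes(beats)
  if (!length(bt)) stop("cannot synthesise a waveform from zero beats")
  if (fs < 50) stop("fs must be at least 50 Hz")
  if (length(bt) > 1L && modality == "pulse" &&
      6 * pulseWidth >= min(diff(bt)))
    stop("overlapping pulses: pulse width too large for the minimum interval")
  duration <- bt[length(bt)] + 0.5
  t <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(t))
  if (modality == "pulse") {
    lobes <- list(c(0, 1, pulseWidth))
  } else {
    lobes <- list(c(-0.020, -0.15, 0.010),  # Q
                  c(0, 1, 0.008),           # R
                  c(0.025, -0.30, 0.012))   # S
  }
  for (tb in bt) {
    for (lb in lobes) {
      lo <- max(1L, floor((tb + lb[1] - 5 * lb[3]) * fs) + 1L)
      hi <- min(length(t), ceiling((tb + lb[1] + 5 * lb[3]) * fs) + 1L)
      idx <- lo:hi
      x[idx] <- x[idx] + lb[2] * exp(-((t[idx] - tb - lb[1])^2) / (2 * lb[3]^2))
    }
  }
  if (is.finite(snrDb)) {
    set.seed(seed)
    noiseSd <- sqrt(stats::var(x) / 10^(snrDb / 10))
    x <- x + rnorm(length(x), 0, noiseSd)
  }
  RawSignal(x, fs, modality = if (modality == "ecg") "ecg" else "pulse")
}

#' Configuration for a labelled question-session
#'
#' The protocol schedule: a rest baseline, then alternating question
#' episodes and rests. Defaults: 15-min baseline, six 1-min questions with
#' 2-min rests, half of the questions lies. The lie effect is a transient
#' sympathetic-like perturbation applied over each lie span: an
#' instantaneous mean-RR decrease (default 5%) and an HF-modulation
#' reduction (default 40%).
#'
#' @param baselineDuration baseline length in seconds (default 900).
#' @param nQuestions number of questions (default 6).
#' @param questionWindow active-state span per question in seconds
#'   (default 60).
#' @param restBetween rest between questions in seconds (default 120).
#' @param lieFraction fraction of questions that are lies (default 0.5).
#' @param lieRRDrop fractional mean-RR decrease during lie spans
#'   (default 0.05; 0 disables).
#' @param lieHFReduction fractional HF-amplitude reduction during lie spans
#'   (default 0.4; 0 disables).
#' @param seed integer seed (drives the lie-label placement).
#' @return list of class \code{"SessionConfig"}.
#' @export
sessionConfig <- function(baselineDuration = 900, nQuestions = 6,
                          questionWindow = 60, restBetween = 120,
                          lieFraction = 0.5, lieRRDrop = 0.05,
                          lieHFReduction = 0.4, seed = 1) {
  if (lieFraction < 0 || lieFraction > 1)
    stop("lieFraction must be in [0, 1]")
  structure(list(baselineDuration = baselineDuration,
                 nQuestions = as.integer(nQuestions),
                 questionWindow = questionWindow, restBetween = restBetween,
                 lieFraction = lieFraction, lieRRDrop = lieRRDrop,
                 lieHFReduction = lieHFReduction, seed = as.integer(seed)),
            class = "SessionConfig")
}

#' Simulate a full labelled session
#'
#' Baseline beats follow \code{sim} unchanged; during each lie question
#' span the instantaneous mean RR is lowered by \code{lieRRDrop} and the HF
#' modulation depth by \code{lieHFReduction} (truth spans are unperturbed).
#' Question labels are balanced per \code{lieFraction} and placed by a
#' seeded draw.
#'
#' @param session a \code{\link{sessionConfig}}.
#' @param sim a \code{\link{simulationConfig}} (its \code{duration} is
#'   overridden by the session schedule).
#' @return list of class \code{"SyntheticSession"}: \code{beats}
#'   (\linkS4class{BeatSeries} over the whole session), \code{schedule}
#'   (data.frame \code{question_id}, \code{start_s}, \code{end_s},
#'   \code{label}, \code{y}), \code{baselineSpan}, and
#'   \code{plantedFeatures} (the parameters the perturbation directly
#'   targets).
#' @export
simulateSession <- function(session = sessionConfig(),
                            sim = simulationConfig()) {
  stopifnot(inherits(session, "SessionConfig"),
            inherits(sim, "SimulationConfig"))
  nQ <- session$nQuestions
  if (nQ == 0L) warning("session has no questions: baseline only")
  qStart <- session$baselineDuration +
    (seq_len(nQ) - 1L) * (session$questionWindow + session$restBetween)
  qEnd <- qStart + session$questionWindow
  total <- if (nQ > 0L) qEnd[nQ] else session$baselineDuration
  nLies <- round(session$lieFraction * nQ)
  set.seed(session$seed)
  lieIdx <- if (nQ > 0L) sort(sample(nQ, nLies)) else integer()
  isLie <- seq_len(nQ) %in% lieIdx

  inLie <- function(t) {
    out <- rep(FALSE, length(t))
    for (i in which(isLie)) out <- out | (t >= qStart[i] & t < qEnd[i])
    out
  }
  mods <- list(
    rrFactor = function(t) 1 - session$lieRRDrop * inLie(t),
    hfAmpFactor = function(t) 1 - session$lieHFReduction * inLie(t))
  simFull <- sim
  simFull$duration <- total
  beats <- simulateRR(simFull, modulators = mods)

  schedule <- data.frame(
    question_id = if (nQ > 0L) paste0("Q", seq_len(nQ)) else character(),
    start_s = qStart, end_s = qEnd,
    label = ifelse(isLie, "lie", "truth"),
    y = ifelse(isLie, 0, 1), stringsAsFactors = FALSE)
  structure(list(beats = beats, schedule = schedule,
                 baselineSpan = c(0, session$baselineDuration),
                 plantedFeatures = c("AVNN", "HF_POWER", "HF_NORM"),
                 session = session, sim = simFull),
            class = "SyntheticSession")
}

#' Simulate a calibrated cohort with planted discriminative features
#'
#' Directly synthesises baseline-calibrated active-state windows for a
#' cohort (bypassing waveform and HRV extraction): every feature of every
#' window is standard normal, except that the planted features of lie
#' windows are shifted by \code{effectD} baseline SDs. The default of 48
#' windows per class matches a session protocol of three 1-min lie
#' questions and three truth questions at roughly one beat per second
#' under the 30-s / 2-beat-step convention. The default cohort size of 20
#' keeps roughly ten participants in each sign-split group: the scoring
#' function divides by a per-group sample SD, which is unstable in groups
#' much smaller than that (see the methods vignette).
#'
#' @param nParticipants cohort size (default 20).
#' @param planted feature names carrying the shift (default PNN50, PAS,
#'   HF_PEAK -- arbitrary short-term choices).
#' @param effectD planted shift in baseline-SD units (default 1.5).
#' @param windowsPerClass lie and truth windows per participant
#'   (default 48).
#' @param seed integer seed.
#' @param featureNames row names of the synthetic matrices.
#' @return list of \linkS4class{HRVWindowMatrix} objects (one per
#'   participant) with labels in \code{colData}.
#' @export
simulateCalibratedCohort <- function(nParticipants = 20,
                                     planted = c("PNN50", "PAS", "HF_PEAK"),
                                     effectD = 1.5, windowsPerClass = 48,
                                     seed = 1,
                                     featureNames = hrvFeatureNames()) {
  stopifnot(all(planted %in% featureNames))
  set.seed(seed)
  lapply(seq_len(nParticipants), function(p) {
    nW <- 2L * windowsPerClass
    y <- rep(c(0, 1), each = windowsPerClass)
    m <- matrix(rnorm(length(featureNames) * nW), nrow = length(featureNames),
                dimnames = list(featureNames, NULL))
    m[planted, y == 0] <- m[planted, y == 0] + effectD
    starts <- seq(900, by = 30, length.out = nW)
    HRVWindowMatrix(m, windowStart = starts, windowEnd = starts + 30,
                    y = y, questionId = paste0("Q", rep(1:6, length.out = nW)))
  })
}

#' Write the canonical fixture suite
#'
#' Generates the small plain-text fixtures the package's tests and examples
#' use: NN-interval files (constant, alternating, white-noise), a
#' noise-free pulse waveform CSV, one labelled session (NN file + session
#' CSV), and a pair of feature-matrix CSVs constructed to be equivalent
#' within a 0.5-SD margin. Bit-reproducible for a fixed seed.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the vector of files written.
#' @export
makeFixtureSuite <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  put <- function(fn) { written <<- c(written, fn); fn }
  set.seed(seed)

  writeNNFile(rep(900, 120), put(file.path(dir, "constant_120.nn")))
  writeNNFile(rep(c(800, 900), 60), put(file.path(dir, "alternating_120.nn")))
  writeNNFile(900 + rnorm(1000, 0, 30),
              put(file.path(dir, "white_noise_1000.nn")))

  b <- simulateRR(simulationConfig(duration = 120, noiseSd = 0, seed = seed))
  w <- simulateWaveform(b, "pulse", fs = 100)
  df <- data.frame(time_s = seq_along(w@samples) / w@samplingRate -
                     1 / w@samplingRate,
                   amplitude = w@samples)
  write.csv(df, put(file.path(dir, "pulse_noise_free.csv")), row.names = FALSE)

  ses <- simulateSession(sessionConfig(seed = seed),
                         simulationConfig(seed = seed))
  writeNNFile(nnIntervals(ses$beats), put(file.path(dir, "session.nn")))
  write.csv(ses$schedule[, c("question_id", "start_s", "end_s", "label")],
            put(file.path(dir, "session_schedule.csv")), row.names = FALSE)

  ## paired matrices: B = A + noise at 0.1 x d x SD, inside a d = 0.5 margin
  nW <- 200L
  a <- matrix(rnorm(39 * nW, mean = rep(seq(10, 48, length.out = 39), nW),
                    sd = 2),
              nrow = 39, dimnames = list(hrvFeatureNames(), NULL))
  bMat <- a + matrix(rnorm(39 * nW, 0, 0.1 * 0.5 * 2), nrow = 39)
  starts <- seq(0, by = 30, length.out = nW)
  writeFeatureMatrix(HRVWindowMatrix(a, starts, starts + 60),
                     put(file.path(dir, "paired_equivalent_A.csv")))
  writeFeatureMatrix(HRVWindowMatrix(bMat, starts, starts + 60),
                     put(file.path(dir, "paired_equivalent_B.csv")))
  invisible(written)
}
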