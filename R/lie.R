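## The lie-detection pipeline: baseline calibration, per-participant
## lie/truth means, sign-split feature scoring, per-participant
## random-forest classification against a majority-vote baseline.

#' Per-feature baseline statistics
#'
#' Mean and sample standard deviation of each HRV parameter over the
#' baseline (rest) windows; the calibration reference for everything that
#' follows. Features with zero or non-finite baseline SD are flagged
#' unusable.
#'
#' @param baseline an \linkS4class{HRVWindowMatrix} of baseline windows
#'   (>= 10 windows), or a plain features x windows matrix.
#' @return list with \code{mu}, \code{sigma} (named numeric), \code{usable}
#'   (logical), \code{nWindows}.
#' @export
computeBaselineStats <- function(baseline) {
  m <- if (is(baseline, "HRVWindowMatrix")) featureMatrix(baseline)
       else as.matrix(baseline)
  if (ncol(m) < 10L)
    stop("insufficient baseline: need at least 10 windows, got ", ncol(m))
  mu <- apply(m, 1, function(v) mean(v[is.finite(v)]))
  sigma <- apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  })
  usable <- is.finite(sigma) & sigma > 0 & is.finite(mu)
  list(mu = mu, sigma = sigma, usable = usable, nWindows = ncol(m))
}

#' Calibrate features to baseline
#'
#' Elementwise \code{(x - mu) / sigma}: each feature is expressed in
#' baseline standard deviations from its baseline mean, so a larger
#' calibrated value means a larger departure from rest (sign preserved).
#'
#' @param x named numeric vector (one window) or features x windows matrix.
#' @param stats baseline statistics from \code{\link{computeBaselineStats}}.
#' @param strict error on unusable (zero-sigma) features instead of
#'   returning NA for them (default FALSE).
#' @return calibrated vector or matrix; unusable features are NA (or an
#'   error under \code{strict}).
#' @export
calibrate <- function(x, stats, strict = FALSE) {
  sigma <- stats$sigma
  if (strict && any(!stats$usable[if (is.matrix(x)) rownames(x) else names(x)]))
    stop("unusable feature requested (zero baseline standard deviation)")
  sigma[!stats$usable] <- NA_real_
  if (is.matrix(x)) (x - stats$mu[rownames(x)]) / sigma[rownames(x)]
  else (x - stats$mu[names(x)]) / sigma[names(x)]
}

#' Calibrated, labelled active-state windows for one participant
#'
#' For each question span, extracts 30-s windows stepping 2 beats (the
#' active-state convention), calibrates every window against the baseline
#' statistics, and labels it with the question's truth/lie label (y = 1
#' truth, y = 0 lie). Question spans yielding no valid window are skipped
#' with a warning.
#'
#' @param beats the participant's full-session \linkS4class{BeatSeries}.
#' @param schedule data.frame with columns \code{question_id},
#'   \code{start_s}, \code{end_s}, \code{y} (see
#'   \code{\link{readSessionCSV}}).
#' @param stats baseline statistics from \code{\link{computeBaselineStats}}.
#' @param config window configuration (default 30-s windows, 2-beat step).
#' @return an \linkS4class{HRVWindowMatrix} of calibrated windows with
#'   \code{y} and \code{questionId} in \code{colData}; zero columns when no
#'   question yields a window.
#' @export
labelActiveWindows <- function(beats, schedule, stats,
                               config = hrvWindowConfig(30, "beat_step",
                                                        stepBeats = 2)) {
  stopifnot(is(beats, "BeatSeries"))
  bt <- beatTimes(beats)
  mats <- list(); starts <- numeric(); ends <- numeric()
  ys <- numeric(); qid <- character(); nb <- integer()
  for (i in seq_len(nrow(schedule))) {
    sel <- bt >= schedule$start_s[i] & bt < schedule$end_s[i]
    if (sum(sel) < config$minBeats) {
      warning(sprintf("question %s: too few beats, skipped",
                      schedule$question_id[i]))
      next
    }
    sub <- BeatSeries(bt[sel])
    wm <- suppressWarnings(extractHRV(sub, config))
    if (!ncol(wm)) {
      warning(sprintf("question %s: no valid window, skipped",
                      schedule$question_id[i]))
      next
    }
    mats[[length(mats) + 1L]] <- calibrate(featureMatrix(wm), stats)
    starts <- c(starts, windowStarts(wm)); ends <- c(ends, windowEnds(wm))
    ys <- c(ys, rep(schedule$y[i], ncol(wm)))
    qid <- c(qid, rep(as.character(schedule$question_id[i]), ncol(wm)))
    nb <- c(nb, SummarizedExperiment::colData(wm)$nBeats)
  }
  if (!length(mats)) {
    return(HRVWindowMatrix(
      matrix(numeric(), 39L, 0L, dimnames = list(hrvFeatureNames(), NULL)),
      numeric(), numeric()))
  }
  HRVWindowMatrix(do.call(cbind, mats), starts, ends, nBeats = nb,
                  y = ys, questionId = qid)
}

#' Per-participant class means of calibrated features
#'
#' \code{ML} is the per-feature mean calibrated value over lie windows
#' (y = 0) and \code{MT} over truth windows (y = 1).
#'
#' @param calib an \linkS4class{HRVWindowMatrix} of calibrated windows with
#'   labels, or a features x windows matrix plus \code{y}.
#' @param y binary labels when \code{calib} is a plain matrix.
#' @return list \code{ML}, \code{MT} (named numeric), \code{NL}, \code{NT}.
#' @export
participantMeans <- function(calib, y = NULL) {
  if (is(calib, "HRVWindowMatrix")) {
    y <- windowLabels(calib)
    calib <- featureMatrix(calib)
  }
  stopifnot(length(y) == ncol(calib), all(y %in% c(0, 1)))
  if (!any(y == 0) || !any(y == 1))
    stop("need at least one lie and one truth window")
  list(ML = rowMeans(calib[, y == 0, drop = FALSE], na.rm = TRUE),
       MT = rowMeans(calib[, y == 1, drop = FALSE], na.rm = TRUE),
       NL = sum(y == 0), NT = sum(y == 1))
}

#' Sign-split of participants for one feature
#'
#' A participant falls in the negative group when the lie-mean and
#' truth-mean of the feature have opposite signs
#' (\code{sign(ML) * sign(MT) < 0}), and otherwise -- including a zero mean
#' -- in the positive group.
#'
#' @param summaries list of per-participant outputs of
#'   \code{\link{participantMeans}}.
#' @param feature feature name.
#' @return list \code{pos}, \code{neg}: integer indices into
#'   \code{summaries}.
#' @export
splitGroups <- function(summaries, feature) {
  neg <- vapply(summaries, function(s)
    sign(s$ML[feature]) * sign(s$MT[feature]) < 0, logical(1))
  list(pos = which(!neg), neg = which(neg))
}

#' Score one feature from its sign-split groups
#'
#' For each group the per-participant values are \code{|MT - ML|}; the
#' group term is mean / sample-SD (the inverse coefficient of variation),
#' and the score is \code{S = beta * term_pos + (1 - beta) * term_neg} with
#' beta = 0.45. An empty or single-member group contributes 0 and is
#' flagged; a zero group SD with nonzero mean makes that term infinite --
#' the term then contributes 0 and the feature is ranked by the finite term
#' alone, flagged. Only a feature with no informative term at all is marked
#' degenerate (excluded from ranking).
#'
#' @param posAbsDiffs,negAbsDiffs numeric vectors of \code{|MT - ML|} for
#'   the positive and negative group participants.
#' @param beta weight of the positive-group term (default 0.45).
#' @return list \code{S}, \code{termPos}, \code{termNeg}, \code{degenerate}
#'   (logical), \code{note}.
#' @examples
#' scoreFeature(c(1, 2, 3), c(2, 4))$S  # 0.45*2 + 0.55*3/sqrt(2)
#' @export
scoreFeature <- function(posAbsDiffs, negAbsDiffs, beta = 0.45) {
  term <- function(v) {
    if (length(v) < 2L)
      return(list(t = 0, informative = FALSE,
                  note = "group too small (term = 0)"))
    s <- stats::sd(v)
    if (s == 0) {
      if (mean(v) == 0)
        return(list(t = 0, informative = FALSE,
                    note = "all-zero group (term = 0)"))
      return(list(t = 0, informative = FALSE,
                  note = "zero group SD (infinite term dropped)"))
    }
    list(t = mean(v) / s, informative = TRUE, note = "")
  }
  tp <- term(posAbsDiffs); tn <- term(negAbsDiffs)
  list(S = beta * tp$t + (1 - beta) * tn$t,
       termPos = tp$t, termNeg = tn$t,
       degenerate = !tp$informative && !tn$informative,
       note = trimws(paste(tp$note, tn$note)))
}

#' Select the top-scoring short-term HRV features
#'
#' Runs the sign-split scoring over the external participants' calibrated
#' windows and returns the \code{k} highest-scoring features. Only
#' short-term parameters are candidates (the physiological response to a
#' question is brief). Participants lacking a label class are excluded
#' with a warning; features whose score is degenerate (infinite or
#' undefined terms) are excluded from ranking. Ties are broken by
#' canonical feature order, deterministically.
#'
#' @param externalWindows list (one element per external participant) of
#'   calibrated, labelled \linkS4class{HRVWindowMatrix} objects.
#' @param beta positive-group weight (default 0.45).
#' @param k number of features to return (default 3).
#' @param candidates candidate feature names (default
#'   \code{\link{shortTermFeatures}}).
#' @return data.frame with \code{feature} and \code{score}, best first
#'   (\code{min(k, scorable)} rows; fewer than \code{k} triggers a
#'   warning).
#' @export
selectFeatures <- function(externalWindows, beta = 0.45, k = 3,
                           candidates = shortTermFeatures()) {
  summaries <- list()
  for (i in seq_along(externalWindows)) {
    s <- tryCatch(participantMeans(externalWindows[[i]]),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning(sprintf("participant %d lacks a label class; excluded from feature selection", i))
      next
    }
    summaries[[length(summaries) + 1L]] <- s
  }
  if (length(summaries) < 2L)
    stop("need at least 2 external participants with both labels")

  scores <- rep(NA_real_, length(candidates))
  names(scores) <- candidates
  for (f in candidates) {
    vals <- vapply(summaries, function(s) abs(s$MT[f] - s$ML[f]), numeric(1))
    if (any(!is.finite(vals))) next
    grp <- splitGroups(summaries, f)
    sc <- scoreFeature(vals[grp$pos], vals[grp$neg], beta)
    if (!sc$degenerate) scores[f] <- sc$S
  }
  scorable <- which(is.finite(scores))
  if (!length(scorable)) stop("feature selection failed: no scorable feature")
  ## descending score; ties broken by canonical (candidate) order
  ord <- scorable[order(-scores[scorable], scorable)]
  kEff <- min(k, length(ord))
  if (kEff < k)
    warning(sprintf("only %d scorable features (requested %d)", kEff, k))
  data.frame(feature = candidates[ord[seq_len(kEff)]],
             score = unname(scores[ord[seq_len(kEff)]]),
             stringsAsFactors = FALSE)
}

#' Majority-vote (naive) classifier
#'
#' Predicts the majority validation label for every window; an exact 50/50
#' tie predicts 1 (truth).
#'
#' @param labels binary validation labels.
#' @return list \code{prediction} (0 or 1) and \code{accuracy} (the
#'   majority fraction, 0-1).
#' @export
naiveClassifier <- function(labels) {
  stopifnot(length(labels) > 0, all(labels %in% c(0, 1)))
  p1 <- mean(labels == 1)
  pred <- if (p1 >= 0.5) 1 else 0
  list(prediction = pred, accuracy = max(p1, 1 - p1))
}

#' Train and evaluate one participant's classifier
#'
#' Repeated seeded stratified Monte-Carlo splits (default 10 repeats,
#' 80/20): in each repeat a random forest (100 trees, default mtry) is
#' trained on the training fraction of the participant's calibrated
#' windows, restricted to the selected features, and its validation
#' accuracy is compared with the majority-vote baseline on the same
#' validation windows.
#'
#' Because consecutive active-state windows overlap heavily (2-beat step)
#' and labels are constant within a question, window-level splits leak:
#' validation windows have near-duplicate neighbours in the training set,
#' which inflates validation accuracy even in the absence of any real
#' effect. \code{splitBy = "question"} offers a leakage-free alternative
#' that holds out one whole question per label as the validation set
#' (requires at least two questions of each label); the window-level split
#' remains the default evaluation convention.
#'
#' @param calib a calibrated, labelled \linkS4class{HRVWindowMatrix}, or a
#'   features x windows matrix plus \code{y}.
#' @param features selected feature names (rows used for training).
#' @param y labels when \code{calib} is a plain matrix.
#' @param nRepeats number of random splits (default 10).
#' @param trainFraction training fraction (default 0.8).
#' @param seed integer seed; the split of repeat r uses \code{seed + r}.
#' @param ntree random-forest size (default 100).
#' @param splitBy \code{"window"} (default: stratified window-level split)
#'   or \code{"question"} (hold out one whole question per label).
#' @param questionId question identifiers per window, needed for
#'   \code{splitBy = "question"} with a plain matrix (taken from
#'   \code{colData} for an \linkS4class{HRVWindowMatrix}).
#' @return list with per-repeat \code{modelAccuracy} and
#'   \code{naiveAccuracy} (percent), and the per-repeat outcome fractions
#'   \code{better}, \code{equal}, \code{worse}.
#' @export
trainEvaluate <- function(calib, features, y = NULL, nRepeats = 10,
                          trainFraction = 0.8, seed = 1, ntree = 100,
                          splitBy = c("window", "question"),
                          questionId = NULL) {
  splitBy <- match.arg(splitBy)
  if (is(calib, "HRVWindowMatrix")) {
    y <- windowLabels(calib)
    questionId <- SummarizedExperiment::colData(calib)$questionId
    calib <- featureMatrix(calib)
  }
  stopifnot(all(features %in% rownames(calib)), length(y) == ncol(calib))
  X <- t(calib[features, , drop = FALSE])
  ok <- stats::complete.cases(X) & y %in% c(0, 1)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (!is.null(questionId)) questionId <- questionId[ok]
  if (length(y) < 10L || length(unique(y)) < 2L)
    stop("participant needs at least 10 labelled windows with both classes")

  if (splitBy == "question") {
    if (is.null(questionId)) stop("splitBy = 'question' needs questionId")
    q0 <- unique(questionId[y == 0]); q1 <- unique(questionId[y == 1])
    if (length(q0) < 2L || length(q1) < 2L)
      stop("question-level splits need at least two questions per label")
  }

  i0 <- which(y == 0); i1 <- which(y == 1)
  n0tr <- max(1L, round(trainFraction * length(i0)))
  n1tr <- max(1L, round(trainFraction * length(i1)))
  if (n0tr >= length(i0)) n0tr <- length(i0) - 1L
  if (n1tr >= length(i1)) n1tr <- length(i1) - 1L

  modelAcc <- naiveAcc <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    set.seed(seed + r)
    if (splitBy == "question") {
      vaQ <- c(sample(q0, 1L), sample(q1, 1L))
      va <- which(questionId %in% vaQ)
      tr <- setdiff(seq_along(y), va)
    } else {
      tr <- c(sample(i0, n0tr), sample(i1, n1tr))
      va <- setdiff(seq_along(y), tr)
    }
    rf <- randomForest::randomForest(x = X[tr, , drop = FALSE],
                                     y = factor(y[tr], levels = c(0, 1)),
                                     ntree = ntree)
    pred <- predict(rf, X[va, , drop = FALSE])
    modelAcc[r] <- 100 * mean(as.numeric(as.character(pred)) == y[va])
    naiveAcc[r] <- 100 * naiveClassifier(y[va])$accuracy
  }
  list(modelAccuracy = modelAcc, naiveAccuracy = naiveAcc,
       better = mean(modelAcc > naiveAcc),
       equal = mean(modelAcc == naiveAcc),
       worse = mean(modelAcc < naiveAcc))
}

#' Cohort-level evaluation report
#'
#' Aggregates per-participant evaluations into cohort mean and sample SD
#' of model accuracy, naive accuracy, and the fractions of repeats in
#' which the model was better than, exactly equal to, or worse than the
#' majority-vote baseline.
#'
#' @param perParticipant list of \code{\link{trainEvaluate}} results.
#' @return list of cohort summaries (JSON-serialisable).
#' @export
aggregateReport <- function(perParticipant) {
  stopifnot(length(perParticipant) >= 1L)
  g <- function(f) vapply(perParticipant, function(p) mean(p[[f]]), numeric(1))
  ms <- function(v) list(mean = mean(v),
                         sd = if (length(v) > 1L) stats::sd(v) else 0)
  list(nParticipants = length(perParticipant),
       modelAccuracy = ms(g("modelAccuracy")),
       naiveAccuracy = ms(g("naiveAccuracy")),
       betterFraction = ms(g("better")),
       equalFraction = ms(g("equal")),
       worseFraction = ms(g("worse")))
}

#' Run the full lie-detection pipeline on a cohort
#'
#' Splits the cohort into an external group (feature selection only;
#' default 20% rounded up, seeded choice) and a training group, selects the
#' top-k short-term features on the external group, trains and evaluates a
#' per-participant classifier on the training group, and aggregates.
#' Feature selection never sees the training participants' windows.
#'
#' @param participantWindows list of calibrated, labelled
#'   \linkS4class{HRVWindowMatrix} objects, one per participant.
#' @param externalFraction fraction of participants reserved for feature
#'   selection (default 0.2, rounded up).
#' @param beta,k see \code{\link{selectFeatures}}.
#' @param nRepeats,trainFraction,splitBy see \code{\link{trainEvaluate}}.
#' @param seed integer seed driving the external-group draw and every
#'   split.
#' @return list with \code{selected} (the feature table), \code{report}
#'   (from \code{\link{aggregateReport}}), \code{perParticipant}, and
#'   \code{externalIdx}.
#' @export
runLiePipeline <- function(participantWindows, externalFraction = 0.2,
                           beta = 0.45, k = 3, nRepeats = 10,
                           trainFraction = 0.8, seed = 1,
                           splitBy = c("window", "question")) {
  splitBy <- match.arg(splitBy)
  nP <- length(participantWindows)
  nExt <- max(2L, ceiling(externalFraction * nP))
  if (nExt >= nP) stop("too few participants to split external/training groups")
  set.seed(seed)
  externalIdx <- sort(sample(nP, nExt))
  selected <- selectFeatures(participantWindows[externalIdx], beta, k)
  trainIdx <- setdiff(seq_len(nP), externalIdx)
  perParticipant <- lapply(seq_along(trainIdx), function(j) {
    trainEvaluate(participantWindows[[trainIdx[j]]], selected$feature,
                  nRepeats = nRepeats, trainFraction = trainFraction,
                  seed = seed * 1000L + j, splitBy = splitBy)
  })
  list(selected = selected, report = aggregateReport(perParticipant),
       perParticipant = perParticipant, externalIdx = externalIdx)
}
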