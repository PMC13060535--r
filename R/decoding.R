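# Population decoding with balanced subsampling and cross-validation,
# and single-neuron information with the 0.06-bit informativeness rule.

#' Decoding hyperparameters
#'
#' @param binMs non-overlapping time-bin width, ms (default 90).
#' @param cvFolds folds of the inner cross-validation (default 10).
#' @param trainFraction fraction of trials in the training partition.
#' @param nSubsampleRepeats balanced-subsampling repeats (default 50).
#' @param minTrialsPerCondition minimum trials per condition cell.
#' @param windowMs post-event summary window, ms (default 450).
#' @param boxConstraint SVM cost parameter (default 1).
#' @return a list of class `ppc_decode_spec`.
#' @export
decodeSpec <- function(binMs = 90, cvFolds = 10L, trainFraction = 0.7,
                       nSubsampleRepeats = 50L,
                       minTrialsPerCondition = 4L, windowMs = 450,
                       boxConstraint = 1) {
  stopifnot(binMs > 0, cvFolds > 1L, trainFraction > 0,
            trainFraction < 1, nSubsampleRepeats > 0L,
            minTrialsPerCondition > 0L, windowMs > 0,
            boxConstraint > 0)
  structure(list(binMs = binMs, cvFolds = as.integer(cvFolds),
                 trainFraction = trainFraction,
                 nSubsampleRepeats = as.integer(nSubsampleRepeats),
                 minTrialsPerCondition = as.integer(minTrialsPerCondition),
                 windowMs = windowMs, boxConstraint = boxConstraint),
            class = "ppc_decode_spec")
}

#' Align trials to task events and truncate to common segment lengths
#'
#' Within-trial segments bounded by consecutive events (pre-first-sound,
#' inter-event, post-reward) vary in length across trials; each segment
#' is truncated to the minimum length across trials so that trials can
#' be stacked into a trials x frames x neurons tensor. Trials missing
#' any requested event are dropped with a warning.
#'
#' @param x a [PPCExperiment-class].
#' @param trialRows trial indices to align (default: all active and
#'   passive trials).
#' @param events ordered event column names (default s1, s2, s3, turn,
#'   reward).
#' @param postFrames frames kept after the last event (default: the
#'   minimum available).
#' @return list with `tensor` (trials x frames x neurons),
#'   `eventIndex` (aligned frame index of each event), and
#'   `trialRows` (retained trials, in order).
#' @export
alignTruncate <- function(x, trialRows = NULL,
                          events = c("s1", "s2", "s3", "turn", "reward"),
                          postFrames = NULL) {
  tr <- trials(x)
  if (is.null(trialRows))
    trialRows <- which(tr$context %in% c("active", "passive"))
  evMat <- as.matrix(as.data.frame(tr[trialRows, events, drop = FALSE]))
  ok <- complete.cases(evMat)
  if (!all(ok)) {
    warning(sprintf("%d trial(s) missing an event were dropped",
                    sum(!ok)))
    trialRows <- trialRows[ok]
    evMat <- evMat[ok, , drop = FALSE]
  }
  if (!length(trialRows)) stop("no alignable trials")
  act <- activity(x)

  preLen <- min(evMat[, 1] - tr$t_start[trialRows]) + 1L
  segLen <- if (ncol(evMat) > 1L)
    vapply(seq_len(ncol(evMat) - 1L), function(k)
      min(evMat[, k + 1L] - evMat[, k]), numeric(1))
  else numeric(0)
  lastPost <- min(tr$t_end[trialRows] - evMat[, ncol(evMat)])
  if (!is.null(postFrames)) lastPost <- min(lastPost, postFrames)

  nFramesAligned <- preLen + sum(segLen) + lastPost
  eventIndex <- preLen + c(0, cumsum(segLen))
  names(eventIndex) <- events

  tensor <- array(NA_real_,
                  dim = c(length(trialRows), nFramesAligned, nrow(act)))
  for (i in seq_along(trialRows)) {
    cols <- c(
      (evMat[i, 1] - preLen + 1L):evMat[i, 1],
      unlist(lapply(seq_along(segLen), function(k)
        evMat[i, k] + seq_len(segLen[k]))),
      evMat[i, ncol(evMat)] + seq_len(lastPost)
    )
    tensor[i, , ] <- t(act[, cols, drop = FALSE])
  }
  list(tensor = tensor, eventIndex = eventIndex, trialRows = trialRows)
}

#' Balanced trial subsets decorrelating two variables
#'
#' Samples, for each repeat, an equal number of trials from every cell
#' of the primary-by-confound condition table (the per-cell minimum),
#' without replacement. Datasets with any cell below
#' `minPerCell` are flagged excluded rather than raising an error.
#'
#' @param trials trial table (DataFrame or data.frame).
#' @param primary,confound column names of the two variables.
#' @param minPerCell minimum count per condition cell (default 4).
#' @param nRepeats number of repeats (default 50).
#' @param seed integer seed.
#' @param trialRows optional subset of trial indices.
#' @return list with `excluded` flag, `perCell` (sampled count per
#'   cell), and `repeats` (list of trial-index vectors).
#' @export
balanceTrials <- function(trials, primary, confound, minPerCell = 4L,
                          nRepeats = 50L, seed = 1L, trialRows = NULL) {
  tr <- as.data.frame(trials)
  if (is.null(trialRows)) trialRows <- seq_len(nrow(tr))
  pv <- as.character(tr[[primary]][trialRows])
  cv <- as.character(tr[[confound]][trialRows])
  ok <- !is.na(pv) & !is.na(cv)
  trialRows <- trialRows[ok]; pv <- pv[ok]; cv <- cv[ok]
  cells <- split(trialRows, paste(pv, cv, sep = "/"))
  if (length(cells) < 2L)
    stop("condition table must have at least two cells")
  counts <- lengths(cells)
  if (any(counts < minPerCell))
    return(list(excluded = TRUE, perCell = min(counts),
                repeats = list()))
  m <- min(counts)
  reps <- withSeed(seed, {
    lapply(seq_len(nRepeats), function(r)
      sort(unlist(lapply(cells, function(idx)
        idx[sample.int(length(idx), m)]), use.names = FALSE)))
  })
  list(excluded = FALSE, perCell = m, repeats = reps)
}

# bin a tensor (trials x frames x neurons) into trials x neurons
# feature matrices, one per time bin
.binFeatures <- function(tensor, binFrames) {
  nF <- dim(tensor)[2]
  nBins <- nF %/% binFrames
  lapply(seq_len(nBins), function(b) {
    cols <- ((b - 1L) * binFrames + 1L):(b * binFrames)
    apply(tensor[, cols, , drop = FALSE], c(1, 3), mean)
  })
}

.trainEval <- function(xtr, ytr, xte, yte, cost) {
  keep <- apply(xtr, 2, sd) > 0
  if (!any(keep)) return(50)
  fit <- tryCatch(
    e1071::svm(xtr[, keep, drop = FALSE], ytr, kernel = "linear",
               cost = cost, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(50)
  pred <- predict(fit, xte[, keep, drop = FALSE])
  100 * mean(pred == yte)
}

#' Linear population decoding over time bins
#'
#' For each non-overlapping time bin, features are the per-neuron mean
#' activity in the bin. Trials are split into a stratified training
#' partition (`trainFraction`) and test partition; per-neuron
#' z-scoring parameters are fit on the training partition only. Within
#' the training partition a stratified `cvFolds`-fold split yields one
#' linear max-margin classifier per fold, each evaluated on the
#' held-out test partition; bin accuracy is their mean. A
#' shuffled-label control is computed identically.
#'
#' @param tensor trials x frames x neurons tensor from
#'   [alignTruncate()] (subset to the decoded trials).
#' @param labels binary labels, one per trial.
#' @param spec a [decodeSpec()].
#' @param frameRate Hz, used to convert `binMs` to frames.
#' @param eventIndex optional named aligned event positions; when
#'   given, mean accuracy in the `windowMs` window after each event is
#'   reported.
#' @param neurons optional neuron index subset.
#' @param seed integer seed.
#' @param shuffle compute the shuffled-label control (default TRUE).
#' @return list with `accuracy` (per bin, %), `shuffled` (per bin, %),
#'   `binCenters` (frames), and `windowAccuracy` (per event, %).
#' @export
decodePopulation <- function(tensor, labels, spec = decodeSpec(),
                             frameRate = 30, eventIndex = NULL,
                             neurons = NULL, seed = 1L,
                             shuffle = TRUE) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must be binary")
  labels <- droplevels(labels)
  if (!is.null(neurons))
    tensor <- tensor[, , neurons, drop = FALSE]
  binFrames <- max(1L, as.integer(round(spec$binMs / 1000 * frameRate)))
  feats <- .binFeatures(tensor, binFrames)
  n <- length(labels)

  runOnce <- function(lab, seedOffset) {
    withSeed(seed + seedOffset, {
      # stratified train/test split
      testIdx <- unlist(lapply(levels(lab), function(l) {
        idx <- which(lab == l)
        nTest <- max(1L, round((1 - spec$trainFraction) * length(idx)))
        sample(idx, nTest)
      }))
      trainIdx <- setdiff(seq_len(n), testIdx)
      foldOf <- integer(n)
      k <- min(spec$cvFolds, min(table(lab[trainIdx])))
      if (k < 2L) stop("too few trials per class for cross-validation")
      foldOf[trainIdx] <- .stratifiedFolds(as.character(lab[trainIdx]), k)
      vapply(feats, function(fm) {
        mu <- colMeans(fm[trainIdx, , drop = FALSE])
        sg <- apply(fm[trainIdx, , drop = FALSE], 2, sd)
        sg[sg == 0] <- 1
        fz <- sweep(sweep(fm, 2, mu), 2, sg, "/")
        acc <- vapply(seq_len(k), function(f) {
          tri <- trainIdx[foldOf[trainIdx] != f]
          .trainEval(fz[tri, , drop = FALSE], lab[tri],
                     fz[testIdx, , drop = FALSE], lab[testIdx],
                     spec$boxConstraint)
        }, numeric(1))
        mean(acc)
      }, numeric(1))
    })
  }

  accuracy <- runOnce(labels, 0L)
  shuffled <- if (shuffle) {
    labShuf <- withSeed(seed + 777L, sample(labels))
    runOnce(labShuf, 1L)
  } else NULL

  binCenters <- (seq_along(feats) - 0.5) * binFrames
  windowAccuracy <- NULL
  if (!is.null(eventIndex)) {
    wFrames <- spec$windowMs / 1000 * frameRate
    windowAccuracy <- vapply(eventIndex, function(ev) {
      sel <- binCenters >= ev & binCenters < ev + wFrames
      if (!any(sel)) return(NA_real_)
      mean(accuracy[sel])
    }, numeric(1))
  }
  list(accuracy = accuracy, shuffled = shuffled,
       binCenters = binCenters, windowAccuracy = windowAccuracy)
}

#' Neuron subsets for decoding comparisons
#'
#' `by_type_all`: all neurons of each type. `n_matched_random`: random
#' subsets of each type matched to the smallest type count.
#' `top_informative`: the top-ranked neurons by peak information,
#' matched to the smallest type count.
#'
#' @param cellTypes factor of per-neuron labels.
#' @param mode subset mode.
#' @param info per-neuron peak information (bits); required for
#'   `top_informative`.
#' @param seed integer seed for the random subsets.
#' @return named list of neuron index vectors.
#' @export
subsamplePopulations <- function(cellTypes,
                                 mode = c("by_type_all",
                                          "n_matched_random",
                                          "top_informative"),
                                 info = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cellTypes <- as.factor(cellTypes)
  counts <- table(cellTypes)
  if (!length(counts) || any(counts == 0L)) stop("empty cell type")
  if (mode == "by_type_all") {
    lapply(setNames(nm = levels(cellTypes)),
           function(l) which(cellTypes == l))
  } else if (mode == "n_matched_random") {
    m <- min(counts)
    withSeed(seed, lapply(setNames(nm = levels(cellTypes)), function(l)
      sort(sample(which(cellTypes == l), m))))
  } else {
    if (is.null(info)) stop("top_informative requires peak information")
    m <- min(counts)
    list(top = order(info, decreasing = TRUE)[seq_len(m)])
  }
}

# mutual information (bits) of a 2x2 confusion table
.binaryMI <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0)
      s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  max(0, s)
}

# per-class Gaussian emission fit; near-zero variances floored so that
# noiseless (deterministic) channels decode by nearest class mean
.fitEmission <- function(xtr, ytr, model = c("gaussian", "poisson")) {
  model <- match.arg(model)
  lev <- levels(ytr)
  if (model == "gaussian") {
    mu <- vapply(lev, function(l) mean(xtr[ytr == l]), numeric(1))
    sg <- vapply(lev, function(l) sd(xtr[ytr == l]), numeric(1))
    sg[!is.finite(sg) | sg < 1e-9] <- 1e-9
    if (all(sg <= 1e-9) && abs(mu[1] - mu[2]) < 1e-12) return(NULL)
    list(model = "gaussian", mu = mu, sg = sg, lev = lev)
  } else {
    lam <- vapply(lev, function(l) mean(pmax(xtr[ytr == l], 0)),
                  numeric(1))
    lam[lam < 1e-9] <- 1e-9
    list(model = "poisson", lam = lam, lev = lev)
  }
}

.mapDecode <- function(em, xte) {
  if (em$model == "gaussian") {
    ll1 <- dnorm(xte, em$mu[1], em$sg[1], log = TRUE)
    ll2 <- dnorm(xte, em$mu[2], em$sg[2], log = TRUE)
  } else {
    ll1 <- stats::dpois(round(pmax(xte, 0)), em$lam[1], log = TRUE)
    ll2 <- stats::dpois(round(pmax(xte, 0)), em$lam[2], log = TRUE)
  }
  em$lev[ifelse(ll2 > ll1, 2L, 1L)]
}

#' Single-neuron information about a task variable
#'
#' An instantaneous Bayesian decoder: at each aligned frame, per-class
#' emission densities are fit on training folds and the
#' maximum-posterior class is decoded for held-out trials (flat
#' prior). The per-frame information is the mutual information (bits)
#' of the resulting decoded-vs-true confusion table, accumulated over
#' folds. Peak information is taken over `window` (for sound, the
#' stimulus-locked epoch; full trial otherwise); a neuron is
#' informative iff its peak exceeds `threshold` bits.
#'
#' @param trialFrames trials x frames matrix of one neuron's aligned
#'   activity.
#' @param labels binary labels, one per trial.
#' @param window frame indices over which the peak is taken (default:
#'   all frames).
#' @param emission `"gaussian"` (default) or `"poisson"` (for event
#'   counts).
#' @param folds cross-validation folds (default 5).
#' @param threshold informativeness threshold in bits (default 0.06).
#' @param seed integer seed for fold assignment.
#' @return list with `information` (bits per frame), `peak`,
#'   `peakFrame` and `informative`.
#' @export
singleNeuronInformation <- function(trialFrames, labels, window = NULL,
                                    emission = c("gaussian", "poisson"),
                                    folds = 5L, threshold = 0.06,
                                    seed = 1L) {
  emission <- match.arg(emission)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must be binary")
  nT <- nrow(trialFrames)
  nF <- ncol(trialFrames)
  if (is.null(window)) window <- seq_len(nF)
  k <- min(folds, min(table(labels)))
  if (k < 2L) stop("too few trials per class")
  foldOf <- withSeed(seed, .stratifiedFolds(as.character(labels), k))
  lev <- levels(labels)

  info <- vapply(seq_len(nF), function(t) {
    xcol <- trialFrames[, t]
    tab <- matrix(0, 2, 2, dimnames = list(lev, lev))
    for (f in seq_len(k)) {
      tri <- foldOf != f
      em <- .fitEmission(xcol[tri], labels[tri], emission)
      if (is.null(em)) next
      pred <- .mapDecode(em, xcol[!tri])
      for (l1 in lev) for (l2 in lev)
        tab[l1, l2] <- tab[l1, l2] +
          sum(pred == l1 & labels[!tri] == l2)
    }
    if (sum(tab) == 0) return(0)
    .binaryMI(tab)
  }, numeric(1))

  peakFrame <- window[which.max(info[window])]
  peak <- info[peakFrame]
  list(information = info, peak = peak, peakFrame = peakFrame,
       informative = peak > threshold)
}
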