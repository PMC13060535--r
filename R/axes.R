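# Population-activity axes: coding directions from mean-vector
# differences, cross-validated trial projections, and relationships
# between pre-stimulus engagement, stimulus responses and behavior.

#' Compute a population-activity axis
#'
#' The axis is the difference between two per-neuron mean vectors,
#' normalized to unit L2 norm.
#'
#' @param meanA,meanB per-neuron mean activity vectors.
#' @param kind axis kind (`"engagement"`, `"sound"`, `"photostim"`).
#' @param foldId optional cross-validation fold index.
#' @param trainingTrials optional indices of the trials used.
#' @param tol degenerate-axis tolerance on the difference norm.
#' @return an [AxisModel-class].
#' @examples
#' computeAxis(c(0, 0), c(3, 4), kind = "engagement")
#' @export
computeAxis <- function(meanA, meanB, kind = "engagement",
                        foldId = NA_integer_,
                        trainingTrials = integer(), tol = 1e-12) {
  if (length(meanA) != length(meanB))
    stop("mean vectors must have the same length")
  d <- meanA - meanB
  nrm <- sqrt(sum(d^2))
  if (!is.finite(nrm) || nrm < tol)
    stop("degenerate axis: mean vectors are (near-)identical")
  new("AxisModel", weights = d / nrm, axisKind = kind,
      foldId = as.integer(foldId),
      trainingTrials = as.integer(trainingTrials))
}

#' Mean-vector contrasts defining each axis
#'
#' Sound axis: post- vs pre-stimulus mean vectors on sound-only
#' trials. Photostim axis: post-stimulus means on sound+photostim vs
#' sound-only trials. Engagement axis: pre-stimulus means on active vs
#' passive trials.
#'
#' @param x a [PPCExperiment-class].
#' @param kind axis kind.
#' @param windows a [windowSpec()].
#' @param trialRows optional subset of trial indices (e.g. a training
#'   fold); defaults to all trials.
#' @return list with per-neuron vectors `meanA`, `meanB` (the axis is
#'   `meanA - meanB` after normalization).
#' @export
axisContrasts <- function(x, kind = c("engagement", "sound", "photostim"),
                          windows = windowSpec(), trialRows = NULL) {
  kind <- match.arg(kind)
  tr <- trials(x)
  if (is.null(trialRows)) trialRows <- seq_len(nrow(tr))
  off <- .windowOffsets(x, windows)
  inCtx <- tr$context %in% c("active", "passive")
  pick <- function(cond) intersect(trialRows, which(cond))
  if (kind == "sound") {
    rows <- pick(inCtx & !tr$photostim)
    if (!length(rows)) stop("no sound-only trials for sound axis")
    list(meanA = rowMeans(.trialWindowMeans(x, rows, off$post)),
         meanB = rowMeans(.trialWindowMeans(x, rows, off$pre)))
  } else if (kind == "photostim") {
    rowsP <- pick(inCtx & tr$photostim)
    rowsS <- pick(inCtx & !tr$photostim)
    if (!length(rowsP) || !length(rowsS))
      stop("missing trial type for photostim axis")
    list(meanA = rowMeans(.trialWindowMeans(x, rowsP, off$post)),
         meanB = rowMeans(.trialWindowMeans(x, rowsS, off$post)))
  } else {
    rowsA <- pick(tr$context == "active")
    rowsP <- pick(tr$context == "passive")
    if (!length(rowsA) || !length(rowsP))
      stop("missing context for engagement axis")
    list(meanA = rowMeans(.trialWindowMeans(x, rowsA, off$preEng)),
         meanB = rowMeans(.trialWindowMeans(x, rowsP, off$preEng)))
  }
}

# stratified fold assignment over trial rows; strata with fewer trials
# than folds are spread round-robin
.stratifiedFolds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated axis projections
#'
#' Trials are partitioned into `kFolds` non-overlapping folds
#' (stratified by context and sound side); for each fold the axis is
#' fit on the other folds' trials and the held-out trials are
#' projected onto it (dot product per frame). Every trial is projected
#' exactly once; per-trial pre- and post-stimulus scalar summaries are
#' the mean projection over the corresponding windows.
#'
#' @param x a [PPCExperiment-class].
#' @param kind axis kind, see [axisContrasts()].
#' @param kFolds number of folds (default 4).
#' @param windows a [windowSpec()].
#' @param frames projection window in frames relative to the
#'   alignment event (default 1 s before to 1.5 s after at the session
#'   frame rate).
#' @param seed seed for the fold assignment.
#' @return list with `projections` (frames x trials matrix), `trials`
#'   (DataFrame: trial row, fold, pre/post scalars), and `axes` (one
#'   [AxisModel-class] per fold).
#' @export
crossvalProject <- function(x, kind = c("engagement", "sound",
                                        "photostim"),
                            kFolds = 4L, windows = windowSpec(),
                            frames = NULL, seed = 1L) {
  kind <- match.arg(kind)
  tr <- trials(x)
  fr <- frameRate(x)
  if (is.null(frames))
    frames <- seq(-as.integer(round(fr)), as.integer(round(1.5 * fr)))
  rows <- which(tr$context %in% c("active", "passive"))
  if (length(rows) < kFolds) stop("too few trials for cross-validation")
  strata <- paste(tr$context[rows], tr$side[rows], tr$photostim[rows])
  fold <- withSeed(seed, .stratifiedFolds(strata, kFolds))

  act <- activity(x)
  off <- .windowOffsets(x, windows)
  preRel <- which(frames %in% off$preEng)
  postRel <- which(frames %in% off$post)

  proj <- matrix(NA_real_, nrow = length(frames), ncol = length(rows))
  axes <- vector("list", kFolds)
  for (f in seq_len(kFolds)) {
    trainRows <- rows[fold != f]
    testRows <- rows[fold == f]
    con <- axisContrasts(x, kind, windows, trialRows = trainRows)
    axes[[f]] <- computeAxis(con$meanA, con$meanB, kind = kind,
                             foldId = f, trainingTrials = trainRows)
    w <- axisWeights(axes[[f]])
    for (j in seq_along(testRows)) {
      ev <- tr$s1[testRows[j]]
      cols <- ev + frames
      ok <- cols >= 1L & cols <= ncol(act)
      pj <- rep(NA_real_, length(frames))
      pj[ok] <- as.numeric(crossprod(w, act[, cols[ok], drop = FALSE]))
      proj[, which(rows == testRows[j])] <- pj
    }
  }
  list(
    projections = proj,
    trials = DataFrame(
      trial = rows, fold = fold,
      pre = colMeans(proj[preRel, , drop = FALSE], na.rm = TRUE),
      post = colMeans(proj[postRel, , drop = FALSE], na.rm = TRUE),
      context = tr$context[rows]
    ),
    axes = axes,
    frames = frames
  )
}

#' Engagement-response coupling across trials
#'
#' Pearson correlation and least-squares slope between per-trial
#' pre-stimulus engagement projections and per-trial post-stimulus
#' response projections (contexts pooled).
#'
#' @param engagementPre,responsePost per-trial scalars.
#' @return list with `r`, `slope`, `p`, `n`.
#' @export
engagementResponseCoupling <- function(engagementPre, responsePost) {
  ok <- is.finite(engagementPre) & is.finite(responsePost)
  xv <- engagementPre[ok]
  yv <- responsePost[ok]
  if (length(xv) < 3L) stop("need at least 3 paired trials")
  if (sd(xv) == 0 || sd(yv) == 0) {
    warning("zero variance; coupling undefined")
    return(list(r = NaN, slope = NaN, p = NaN, n = length(xv)))
  }
  ct <- cor.test(xv, yv)
  list(r = unname(ct$estimate),
       slope = unname(coef(lm(yv ~ xv))[2]),
       p = ct$p.value, n = length(xv))
}

#' Behavioral performance by engagement bin
#'
#' Bins active-context trials by their pre-stimulus engagement
#' projection, computes the fraction correct per bin (bins with fewer
#' than `minTrials` trials are dropped), and fits a linear regression
#' of fraction correct on bin centers.
#'
#' @param engagementPre per-trial engagement scalars.
#' @param correct per-trial logical outcomes.
#' @param binEdges bin boundaries (default -1 to 2 in steps of 0.5).
#' @param minTrials minimum trials per retained bin (default 5).
#' @return list with `bins` (data.frame: center, n, fraction_correct)
#'   and `slope` of the regression.
#' @export
performanceByEngagement <- function(engagementPre, correct,
                                    binEdges = c(-1, -0.5, 0, 0.5, 1,
                                                 1.5, 2),
                                    minTrials = 5L) {
  ok <- is.finite(engagementPre) & !is.na(correct)
  ep <- engagementPre[ok]
  cr <- as.logical(correct[ok])
  bin <- cut(ep, binEdges, include.lowest = TRUE)
  centers <- (binEdges[-1] + binEdges[-length(binEdges)]) / 2
  nPer <- as.integer(table(bin))
  frac <- vapply(levels(bin),
                 function(b) mean(cr[which(bin == b)]), numeric(1))
  keep <- nPer >= minTrials
  if (!any(keep)) stop("all engagement bins underpopulated")
  bins <- data.frame(center = centers[keep], n = nPer[keep],
                     fraction_correct = unname(frac[keep]))
  slope <- if (nrow(bins) >= 2L)
    unname(coef(lm(fraction_correct ~ center, data = bins))[2])
  else NA_real_
  list(bins = bins, slope = slope)
}

#' Cell-type contribution to an axis
#'
#' Mean absolute projection weight per cell type, with raw-weight
#' summaries.
#'
#' @param axis an [AxisModel-class].
#' @param cellTypes factor of per-neuron labels.
#' @return data.frame with one row per cell type.
#' @export
cellTypeAxisContribution <- function(axis, cellTypes) {
  w <- axisWeights(axis)
  if (length(cellTypes) != length(w))
    stop("cellTypes must label every neuron on the axis")
  if (anyNA(cellTypes)) stop("unknown cell-type label")
  cellTypes <- as.factor(cellTypes)
  data.frame(
    cell_type = levels(cellTypes),
    n = as.integer(table(cellTypes)),
    mean_abs_weight = as.numeric(tapply(abs(w), cellTypes, mean)),
    mean_weight = as.numeric(tapply(w, cellTypes, mean)),
    sd_weight = as.numeric(tapply(w, cellTypes, sd))
  )
}
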