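# Modulation indices (sound, photostimulation, engagement), shuffle
# significance and functional classification.

#' Analysis windows for modulation indices
#'
#' @param preSoundMs window before stimulus onset used for the
#'   pre-stimulus mean (default 300 ms).
#' @param postSoundMs window after stimulus onset used for the
#'   response mean (default 1000 ms).
#' @param preEngagementMs pre-stimulus window used for the engagement
#'   index (default 300 ms).
#' @return a list of class `ppc_window_spec`.
#' @export
windowSpec <- function(preSoundMs = 300, postSoundMs = 1000,
                       preEngagementMs = 300) {
  stopifnot(preSoundMs > 0, postSoundMs > 0, preEngagementMs > 0)
  structure(list(preSoundMs = preSoundMs, postSoundMs = postSoundMs,
                 preEngagementMs = preEngagementMs),
            class = "ppc_window_spec")
}

#' Contrast-form modulation index
#'
#' `(rB - rA) / (rA + rB)`, the normalized contrast used for the
#' sound, photostimulation and engagement indices. When both inputs
#' are zero the index is 0 by convention; a non-positive denominator
#' with a nonzero numerator yields NaN with a warning (possible when
#' window means dip below zero).
#'
#' @param rA,rB mean responses (vectorized).
#' @return index values; in `[-1, 1]` whenever both inputs are
#'   non-negative.
#' @examples
#' modulationIndex(0.1, 0.3) # 0.5
#' @export
modulationIndex <- function(rA, rB) {
  num <- rB - rA
  den <- rA + rB
  out <- num / den
  zz <- den == 0 & num == 0
  out[zz] <- 0
  bad <- den <= 0 & !zz
  if (any(bad, na.rm = TRUE)) {
    out[which(bad)] <- NaN
    warning("non-positive denominator in modulation index; NaN returned")
  }
  out
}

#' Combine per-side indices
#'
#' Sound and photostimulation indices are computed separately on left-
#' and right-sound trials; the value with the larger absolute magnitude
#' is kept, sign preserved (so strong negative modulation is not
#' masked). A missing side falls back to the other.
#'
#' @param left,right per-neuron index values (vectorized).
#' @return combined index.
#' @export
pickLargerSide <- function(left, right) {
  out <- ifelse(is.na(left), right,
                ifelse(is.na(right), left,
                       ifelse(abs(right) > abs(left), right, left)))
  out
}

#' Shuffle significance for a contrast index
#'
#' The observed index is computed from the two groups' means; a null
#' distribution is built by pooling the per-trial means, permuting
#' group labels `nShuffles` times and recomputing the index. A neuron
#' is called positively modulated iff its observed index exceeds the
#' 97.5th percentile of the null (strict) AND exceeds the magnitude
#' threshold 0.1; negatively modulated iff below the 2.5th percentile
#' AND below -0.1; otherwise unmodulated.
#'
#' @param valuesA,valuesB per-trial window means for the two
#'   conditions being contrasted.
#' @param nShuffles number of label shuffles (default 1000).
#' @param magThreshold magnitude threshold (default 0.1).
#' @param alphaTail one-sided tail mass (default 0.025).
#' @param seed integer seed for the shuffle RNG.
#' @return list with `index` (observed) and `call` (one of
#'   `"positive"`, `"negative"`, `"none"`).
#' @export
shuffleSignificance <- function(valuesA, valuesB, nShuffles = 1000,
                                magThreshold = 0.1, alphaTail = 0.025,
                                seed = NULL) {
  valuesA <- valuesA[is.finite(valuesA)]
  valuesB <- valuesB[is.finite(valuesB)]
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be non-empty")
  obs <- modulationIndex(mean(valuesA), mean(valuesB))
  if (length(valuesA) + length(valuesB) < 2L || is.na(obs)) {
    warning("too few trials for shuffle significance; returning 'none'")
    return(list(index = obs, call = "none"))
  }
  pooled <- c(valuesA, valuesB)
  nA <- length(valuesA)
  n <- length(pooled)
  tot <- sum(pooled)
  null <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(k) {
      ia <- sample.int(n, nA)
      sA <- sum(pooled[ia])
      suppressWarnings(
        modulationIndex(sA / nA, (tot - sA) / (n - nA)))
    }, numeric(1))
  })
  null <- null[is.finite(null)]
  lo <- quantile(null, alphaTail, names = FALSE)
  hi <- quantile(null, 1 - alphaTail, names = FALSE)
  call <- if (obs > hi && obs > magThreshold) "positive"
  else if (obs < lo && obs < -magThreshold) "negative"
  else "none"
  list(index = obs, call = call)
}

# per-trial window means for one alignment; returns neurons x trials
.trialWindowMeans <- function(x, trialRows, offsetFrames) {
  act <- activity(x)
  ev <- trials(x)$s1[trialRows]
  nF <- ncol(act)
  vapply(seq_along(ev), function(k) {
    cols <- ev[k] + offsetFrames
    cols <- cols[cols >= 1L & cols <= nF]
    rowMeans(act[, cols, drop = FALSE])
  }, numeric(nrow(act)))
}

.windowOffsets <- function(x, windows) {
  fr <- frameRate(x)
  list(pre = seq(-as.integer(round(windows$preSoundMs / 1000 * fr)), -1L),
       post = seq(0L, as.integer(round(windows$postSoundMs / 1000 * fr)) - 1L),
       preEng = seq(-as.integer(round(windows$preEngagementMs / 1000 * fr)),
                    -1L))
}

# index + significance for one neuron/one contrast, split by side
.sideContrast <- function(meansA, meansB, sideA, sideB, nShuffles, seed,
                          magThreshold) {
  perSide <- lapply(c("left", "right"), function(s) {
    a <- meansA[sideA == s]
    b <- meansB[sideB == s]
    if (!length(a) || !length(b)) return(NULL)
    shuffleSignificance(a, b, nShuffles = nShuffles, seed = seed,
                        magThreshold = magThreshold)
  })
  keep <- !vapply(perSide, is.null, logical(1))
  perSide <- perSide[keep]
  if (!length(perSide)) return(list(index = NA_real_, call = "none"))
  if (length(perSide) == 1L) return(perSide[[1]])
  iL <- perSide[[1]]$index
  iR <- perSide[[2]]$index
  if (is.na(iL)) return(perSide[[2]])
  if (is.na(iR)) return(perSide[[1]])
  if (abs(iR) > abs(iL)) perSide[[2]] else perSide[[1]]
}

#' Per-neuron modulation indices with shuffle significance
#'
#' Computes, for every neuron: the sound modulation index (SMI) in the
#' active and passive contexts (sound-only trials, pre vs post window,
#' per sound side with the larger-magnitude side kept), the
#' photostimulation modulation index (PMI) in both contexts (post
#' window, sound+photostim vs sound-only trials), the
#' photostimulation response in the spontaneous context (SMI form
#' around the stimulation event), and the engagement index (EI,
#' pre-stimulus window, active vs passive, all trials). Each index
#' carries a shuffle-significance call, and neurons are classified
#' into Sound / Photostim / Sound&Photostim / Unmodulated.
#'
#' The shuffle RNG is seeded per neuron from `seed` so results are
#' reproducible and independent of neuron order.
#'
#' @param x a [PPCExperiment-class].
#' @param windows a [windowSpec()].
#' @param nShuffles shuffles per significance test.
#' @param magThreshold significance magnitude threshold.
#' @param seed master seed.
#' @return a [S4Vectors::DataFrame], one row per neuron.
#' @export
computeModulation <- function(x, windows = windowSpec(),
                              nShuffles = 1000, magThreshold = 0.1,
                              seed = 1L) {
  tr <- trials(x)
  off <- .windowOffsets(x, windows)
  n <- nrow(x)

  sel <- list(
    sa = which(tr$context == "active" & !tr$photostim),
    sp = which(tr$context == "passive" & !tr$photostim),
    pa = which(tr$context == "active" & tr$photostim),
    pp = which(tr$context == "passive" & tr$photostim),
    spont = which(tr$context == "spontaneous"),
    allA = which(tr$context == "active"),
    allP = which(tr$context == "passive")
  )
  wm <- list(
    sa_pre = .trialWindowMeans(x, sel$sa, off$pre),
    sa_post = .trialWindowMeans(x, sel$sa, off$post),
    sp_pre = .trialWindowMeans(x, sel$sp, off$pre),
    sp_post = .trialWindowMeans(x, sel$sp, off$post),
    pa_post = .trialWindowMeans(x, sel$pa, off$post),
    pp_post = .trialWindowMeans(x, sel$pp, off$post),
    spont_pre = .trialWindowMeans(x, sel$spont, off$pre),
    spont_post = .trialWindowMeans(x, sel$spont, off$post),
    allA_pre = .trialWindowMeans(x, sel$allA, off$preEng),
    allP_pre = .trialWindowMeans(x, sel$allP, off$preEng)
  )
  sideOf <- function(rows) as.character(tr$side[rows])

  res <- lapply(seq_len(n), function(i) {
    sd_i <- seed + i
    smiA <- .sideContrast(wm$sa_pre[i, ], wm$sa_post[i, ],
                          sideOf(sel$sa), sideOf(sel$sa),
                          nShuffles, sd_i, magThreshold)
    smiP <- .sideContrast(wm$sp_pre[i, ], wm$sp_post[i, ],
                          sideOf(sel$sp), sideOf(sel$sp),
                          nShuffles, sd_i + 1L, magThreshold)
    pmiA <- .sideContrast(wm$sa_post[i, ], wm$pa_post[i, ],
                          sideOf(sel$sa), sideOf(sel$pa),
                          nShuffles, sd_i + 2L, magThreshold)
    pmiP <- .sideContrast(wm$sp_post[i, ], wm$pp_post[i, ],
                          sideOf(sel$sp), sideOf(sel$pp),
                          nShuffles, sd_i + 3L, magThreshold)
    spont <- shuffleSignificance(wm$spont_pre[i, ], wm$spont_post[i, ],
                                 nShuffles = nShuffles, seed = sd_i + 4L,
                                 magThreshold = magThreshold)
    # EI convention: positive = higher pre-stimulus activity when active
    ei <- shuffleSignificance(wm$allP_pre[i, ], wm$allA_pre[i, ],
                              nShuffles = nShuffles, seed = sd_i + 5L,
                              magThreshold = magThreshold)
    list(smiA = smiA, smiP = smiP, pmiA = pmiA, pmiP = pmiP,
         spont = spont, ei = ei)
  })

  g <- function(f, w) vapply(res, function(r) r[[w]][[f]],
                             if (f == "index") numeric(1) else character(1))
  soundSig <- g("call", "smiA") != "none" | g("call", "smiP") != "none"
  photoSig <- g("call", "spont") != "none"

  DataFrame(
    neuron = rownames(x),
    cell_type = cellTypes(x),
    smi_active = g("index", "smiA"),
    smi_active_call = g("call", "smiA"),
    smi_passive = g("index", "smiP"),
    smi_passive_call = g("call", "smiP"),
    pmi_active = g("index", "pmiA"),
    pmi_active_call = g("call", "pmiA"),
    pmi_passive = g("index", "pmiP"),
    pmi_passive_call = g("call", "pmiP"),
    smi_spont_photostim = g("index", "spont"),
    smi_spont_call = g("call", "spont"),
    ei = g("index", "ei"),
    ei_call = g("call", "ei"),
    functional_class = classifyFunctional(soundSig, photoSig)
  )
}

#' Functional classification from significance flags
#'
#' Sound: sound-significant in at least one context (active or
#' passive) and not photostim-significant (spontaneous context);
#' Photostim: the converse; Sound&Photostim: both; otherwise
#' Unmodulated.
#'
#' @param soundSig,photoSig logical vectors.
#' @return factor with levels Sound, Photostim, Sound&Photostim,
#'   Unmodulated.
#' @export
classifyFunctional <- function(soundSig, photoSig) {
  out <- ifelse(soundSig & photoSig, "Sound&Photostim",
                ifelse(soundSig, "Sound",
                       ifelse(photoSig, "Photostim", "Unmodulated")))
  factor(out, levels = c("Sound", "Photostim", "Sound&Photostim",
                         "Unmodulated"))
}

#' Photostimulation-induced response change
#'
#' `deltaStim = mean post-window response on sound+photostim trials
#' minus mean on sound-only trials`, per neuron, within one context.
#'
#' @param x a [PPCExperiment-class].
#' @param context `"active"` or `"passive"`.
#' @param windows a [windowSpec()].
#' @return named numeric vector, one value per neuron (NaN with a
#'   warning when a trial type is absent).
#' @export
deltaStim <- function(x, context = c("active", "passive"),
                      windows = windowSpec()) {
  context <- match.arg(context)
  tr <- trials(x)
  off <- .windowOffsets(x, windows)
  rowsS <- which(tr$context == context & !tr$photostim)
  rowsP <- which(tr$context == context & tr$photostim)
  if (!length(rowsS) || !length(rowsP)) {
    warning("missing trial type for deltaStim; returning NaN")
    return(setNames(rep(NaN, nrow(x)), rownames(x)))
  }
  mS <- rowMeans(.trialWindowMeans(x, rowsS, off$post))
  mP <- rowMeans(.trialWindowMeans(x, rowsP, off$post))
  setNames(mP - mS, rownames(x))
}

#' Write a modulation table to CSV
#'
#' @param mod result of [computeModulation()].
#' @param file output path.
#' @export
writeModulation <- function(mod, file) {
  write.csv(as.data.frame(mod), file, row.names = FALSE)
  invisible(file)
}
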