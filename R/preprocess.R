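# Fluorescence preprocessing: neuropil correction, rolling-percentile
# dF/F, and a first-difference AR(1) event-extraction stand-in for
# constrained deconvolution.

#' Neuropil correction
#'
#' Subtracts the scaled neuropil signal from the raw somatic
#' fluorescence: `corrected = raw - scale * neuropil`.
#'
#' @param raw raw fluorescence, vector or neurons-by-frames matrix.
#' @param neuropil matched neuropil fluorescence, same shape.
#' @param scale neuropil contamination factor (default 0.7).
#' @return corrected fluorescence, same shape as `raw`.
#' @export
neuropilCorrect <- function(raw, neuropil, scale = 0.7) {
  if (!identical(dim(raw), dim(neuropil)) ||
      length(raw) != length(neuropil))
    stop("raw and neuropil must have identical shape")
  raw - scale * neuropil
}

#' Compute dF/F with a rolling-percentile baseline
#'
#' The baseline at frame i is the 8th percentile of the corrected
#' fluorescence over a window of `halfWindowFrames` frames before and
#' after (clipped at the recording edges), and
#' `dff[i] = (f[i] - b[i]) / b[i]`. Frames whose baseline is not
#' positive are flagged invalid (NaN) with a warning.
#'
#' @param f corrected fluorescence, vector or neurons-by-frames matrix.
#' @param halfWindowFrames window half-width in frames (default 450,
#'   i.e. 15 s at 30 Hz).
#' @param prob baseline percentile (default 0.08).
#' @return dF/F, same shape as `f`.
#' @export
computeDFF <- function(f, halfWindowFrames = 450L, prob = 0.08) {
  stopifnot(halfWindowFrames >= 1L)
  one <- function(v) {
    if (length(v) < 2L) stop("trace must have length > 1")
    b <- cpp_rolling_quantile(as.numeric(v), as.integer(halfWindowFrames),
                              prob)
    bad <- b <= 0
    out <- (v - b) / b
    out[bad] <- NaN
    attr(out, "n_invalid") <- sum(bad)
    out
  }
  if (is.matrix(f)) {
    out <- t(apply(f, 1L, function(v) {
      r <- one(v); attributes(r) <- NULL; r
    }))
    dimnames(out) <- dimnames(f)
    nbad <- sum(!is.finite(out))
    if (nbad > 0)
      warning(sprintf("%d frame(s) with non-positive baseline set to NaN",
                      nbad))
    out
  } else {
    out <- one(f)
    if (attr(out, "n_invalid") > 0)
      warning(sprintf("%d frame(s) with non-positive baseline set to NaN",
                      attr(out, "n_invalid")))
    attr(out, "n_invalid") <- NULL
    out
  }
}

#' Event extraction by AR(1) inversion
#'
#' A transparent stand-in for constrained deconvolution: under an AR(1)
#' calcium model `c[t] = decay * c[t-1] + s[t]`, the innovation
#' `s[t] = max(0, dff[t] - decay * dff[t-1])` recovers impulse times
#' and amplitudes exactly for noiseless AR(1) traces. Events below
#' `threshold` are zeroed.
#'
#' @param dff dF/F trace (vector or neurons-by-frames matrix).
#' @param decayPerFrame AR(1) coefficient in (0, 1); for a transient
#'   with decay constant `tau` seconds at rate `r` Hz this is
#'   `exp(-1 / (tau * r))`.
#' @param threshold minimum event amplitude (default 0.05 a.u.).
#' @return non-negative event amplitudes, same shape as `dff`.
#' @export
extractEvents <- function(dff, decayPerFrame, threshold = 0.05) {
  stopifnot(decayPerFrame > 0, decayPerFrame < 1)
  one <- function(v) {
    if (any(!is.finite(v)))
      warning("non-finite dF/F values propagate to NaN events")
    prev <- c(0, v[-length(v)])
    ev <- pmax(0, v - decayPerFrame * prev)
    ev[ev < threshold & is.finite(ev)] <- 0
    ev
  }
  if (is.matrix(dff)) {
    out <- t(apply(dff, 1L, one))
    dimnames(out) <- dimnames(dff)
    out
  } else one(dff)
}

#' Full fluorescence preprocessing
#'
#' Convenience wrapper: neuropil correction, then rolling-percentile
#' dF/F, then AR(1) event extraction.
#'
#' @inheritParams neuropilCorrect
#' @inheritParams computeDFF
#' @param decayS transient decay constant in seconds used for the AR(1)
#'   coefficient.
#' @param frameRate Hz.
#' @param threshold event threshold.
#' @return list with elements `dff` and `events`.
#' @export
preprocessFluorescence <- function(raw, neuropil, scale = 0.7,
                                   halfWindowFrames = 450L,
                                   decayS = 0.5, frameRate = 30,
                                   threshold = 0.05) {
  f <- neuropilCorrect(raw, neuropil, scale)
  dff <- computeDFF(f, halfWindowFrames)
  gamma <- exp(-1 / (decayS * frameRate))
  list(dff = dff, events = extractEvents(dff, gamma, threshold))
}
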