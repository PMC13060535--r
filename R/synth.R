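# Synthetic session generator: trial-structured multi-cell-type dF/F
# with planted, analytically known effect structure, so every
# downstream stage can be tested against ground truth.

#' Configuration for the synthetic-session generator
#'
#' Defaults emulate a typical imaging session: 270 Pyr, 14 SOM and 31 PV
#' neurons at 30 Hz, 200 active-context trials (with 77.4% planted
#' behavioral accuracy), 150 passive trials, 90 spontaneous
#' photostimulation events at 10 s spacing, photostimulation on one
#' third of active/passive trials, and planted responsive fractions of
#' 25% sound, 4% photostimulation and 2% dual neurons.
#'
#' @param nNeurons named counts for `Pyr`, `SOM`, `PV`.
#' @param frameRate acquisition rate, Hz.
#' @param nTrials named trial counts for `active`, `passive`,
#'   `spontaneous` (spontaneous entries are photostimulation events).
#' @param fracSound,fracPhotostim,fracDual planted responsive fractions;
#'   their sum must not exceed 1.
#' @param effectSound,effectPhotostim planted response amplitudes
#'   (peak dF/F of the exponential transient).
#' @param effectEngagement planted pre-stimulus baseline shift (dF/F per
#'   unit engagement state); sign is class-specific (positive for
#'   sound-responsive, negative for photostim-responsive and
#'   unmodulated neurons, zero for dual).
#' @param sideContrast relative reduction of the non-preferred-side
#'   sound amplitude (0 = no side selectivity).
#' @param coupleSound,couplePhotostim fractional response-gain change
#'   per unit trial-to-trial engagement state; the positive/negative
#'   defaults plant the sign structure of engagement-response coupling.
#' @param baseline constant dF/F baseline.
#' @param noiseSd per-frame i.i.d. Gaussian noise s.d.
#' @param photostimTrialFraction fraction of active/passive trials with
#'   photostimulation.
#' @param accuracy planted mean fraction of correct active trials.
#' @param engagementSlope logistic slope of correctness on the
#'   per-trial engagement state.
#' @param crossTalk additive sound-neuron response on photostimulation
#'   trials (0 disables; negative plants cross-suppression).
#' @param decayS response-transient decay constant, seconds.
#' @param jitterFrames uniform jitter applied to turn/reward frames.
#' @param seed integer seed; the full session is reproducible from it.
#' @return a validated list of class `ppc_synth_config`.
#' @seealso [generateSession()], [generateTrialTable()]
#' @export
synthConfig <- function(nNeurons = c(Pyr = 270L, SOM = 14L, PV = 31L),
                        frameRate = 30,
                        nTrials = c(active = 200L, passive = 150L,
                                    spontaneous = 90L),
                        fracSound = 0.25, fracPhotostim = 0.04,
                        fracDual = 0.02,
                        effectSound = 0.35, effectPhotostim = 0.30,
                        effectEngagement = 0.06,
                        sideContrast = 0.5,
                        coupleSound = 0.3, couplePhotostim = -0.3,
                        baseline = 0.2, noiseSd = 0.10,
                        photostimTrialFraction = 1 / 3,
                        accuracy = 0.774, engagementSlope = 0.8,
                        crossTalk = 0, decayS = 0.5,
                        jitterFrames = 10L, seed = 1L) {
  cfg <- list(nNeurons = nNeurons, frameRate = frameRate,
              nTrials = nTrials, fracSound = fracSound,
              fracPhotostim = fracPhotostim, fracDual = fracDual,
              effectSound = effectSound,
              effectPhotostim = effectPhotostim,
              effectEngagement = effectEngagement,
              sideContrast = sideContrast, coupleSound = coupleSound,
              couplePhotostim = couplePhotostim, baseline = baseline,
              noiseSd = noiseSd,
              photostimTrialFraction = photostimTrialFraction,
              accuracy = accuracy, engagementSlope = engagementSlope,
              crossTalk = crossTalk, decayS = decayS,
              jitterFrames = as.integer(jitterFrames),
              seed = as.integer(seed))
  fr <- c(fracSound, fracPhotostim, fracDual, photostimTrialFraction)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]")
  if (fracSound + fracPhotostim + fracDual > 1)
    stop("responsive fractions must sum to at most 1")
  if (any(cfg$nNeurons <= 0L))
    stop("all neuron counts must be positive")
  if (any(cfg$nTrials <= 0L))
    stop("all trial counts must be positive")
  if (frameRate <= 0) stop("frameRate must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  class(cfg) <- "ppc_synth_config"
  cfg
}

# Mean of the response kernel exp(-j / (decayS * rate)), j = 0..D-1,
# i.e. the expected contribution of a unit-amplitude transient to a
# window mean over D frames starting at the event frame.
kernelWindowMean <- function(frameRate, windowFrames, decayS = 0.5) {
  tauF <- decayS * frameRate
  j <- seq_len(windowFrames) - 1
  mean(exp(-j / tauF))
}

#' Amplitude that plants a target modulation index
#'
#' Inverts the deterministic mapping from transient amplitude to the
#' expected contrast index `(Rpost - Rpre) / (Rpost + Rpre)`, for a
#' response added on a constant baseline and averaged over the
#' post-event window.
#'
#' @param index target index in (-1, 1).
#' @param baseline baseline dF/F.
#' @param frameRate Hz.
#' @param windowS post-window duration, seconds.
#' @param decayS transient decay constant, seconds.
#' @export
amplitudeForIndex <- function(index, baseline, frameRate = 30,
                              windowS = 1, decayS = 0.5) {
  stopifnot(abs(index) < 1, baseline > 0)
  km <- kernelWindowMean(frameRate, round(windowS * frameRate), decayS)
  2 * baseline * index / (km * (1 - index))
}

# shared trial-and-engagement draw; everything downstream of the seed
.generateTrialsCore <- function(config) {
  stopifnot(inherits(config, "ppc_synth_config"))
  fr <- config$frameRate
  toFr <- function(s) as.integer(round(s * fr))
  jit <- function(n) sample(seq(-config$jitterFrames,
                                config$jitterFrames), n, replace = TRUE)

  nA <- as.integer(config$nTrials[["active"]])
  nP <- as.integer(config$nTrials[["passive"]])
  nS <- as.integer(config$nTrials[["spontaneous"]])
  if (any(c(nA, nP, nS) <= 0L)) stop("trial counts must be positive")

  makeBlock <- function(n, context, cursor) {
    side <- sample(rep(c("left", "right"), length.out = n))
    nStim <- as.integer(round(n * config$photostimTrialFraction))
    photostim <- seq_len(n) %in% sample.int(n, nStim)
    e <- rnorm(n, mean = if (context == "active") 1 else 0, sd = 0.35)
    if (context == "active") {
      pCorrect <- plogis(qlogis(config$accuracy) +
                           config$engagementSlope * (e - 1))
      correct <- runif(n) < pCorrect
      choice <- ifelse(correct, side,
                       ifelse(side == "left", "right", "left"))
    } else {
      correct <- rep(NA, n)
      choice <- rep(NA_character_, n)
    }
    t_start <- s1 <- s2 <- s3 <- turn <- reward <- t_end <- integer(n)
    turnJ <- jit(n)
    gapJ <- pmax(jit(n), -10L) # reward stays >= 5 frames after turn
    for (i in seq_len(n)) {
      t_start[i] <- cursor
      s1[i] <- cursor + toFr(3)
      s2[i] <- s1[i] + toFr(1.25)
      s3[i] <- s2[i] + toFr(1.25)
      turn[i] <- s1[i] + toFr(4) + turnJ[i]
      reward[i] <- turn[i] + toFr(0.5) + gapJ[i]
      iti <- if (isTRUE(correct[i]) || context == "passive") 3 else 5
      t_end[i] <- reward[i] + toFr(iti)
      cursor <- t_end[i] + 1L
    }
    list(df = DataFrame(context = context, side = side,
                        photostim = photostim, choice = choice,
                        correct = correct, t_start = t_start, s1 = s1,
                        s2 = s2, s3 = s3, turn = turn, reward = reward,
                        t_end = t_end),
         engagement = e, cursor = cursor)
  }

  a <- makeBlock(nA, "active", 1L)
  p <- makeBlock(nP, "passive", a$cursor)

  # spontaneous context: photostim events at regular 10 s intervals
  cursor <- p$cursor
  spacing <- toFr(10)
  s1 <- cursor + toFr(3) + spacing * (seq_len(nS) - 1L)
  sp <- DataFrame(context = "spontaneous", side = NA_character_,
                  photostim = TRUE, choice = NA_character_,
                  correct = NA,
                  t_start = s1 - toFr(3),
                  s1 = s1, s2 = NA_integer_, s3 = NA_integer_,
                  turn = NA_integer_, reward = NA_integer_,
                  t_end = s1 + toFr(7) - 1L)

  tr <- rbind(a$df, p$df, sp)
  tr$context <- factor(tr$context,
                       levels = c("active", "passive", "spontaneous"))
  list(trials = tr,
       engagement = c(a$engagement, p$engagement, rep(NA_real_, nS)),
       nFrames = max(tr$t_end))
}

#' Generate the trial table of a synthetic session
#'
#' Event frames are monotone within each trial by construction (first,
#' second, third sound onsets, then turn and reward with bounded
#' jitter); photostimulation is flagged on the configured fraction of
#' active and passive trials, and spontaneous-context events occur at
#' regular 10 s intervals.
#'
#' @param config a [synthConfig()].
#' @return a [S4Vectors::DataFrame], one row per trial.
#' @export
generateTrialTable <- function(config) {
  withSeed(config$seed, .generateTrialsCore(config))$trials
}

# expected window means -> planted index values, per class and context
.plantedIndices <- function(config) {
  fr <- config$frameRate
  b <- config$baseline
  kmPost <- kernelWindowMean(fr, as.integer(round(fr)), config$decayS)
  gainS <- function(eBar) max(0, 1 + config$coupleSound * (eBar - 0.5))
  gainP <- function(eBar) max(0, 1 + config$couplePhotostim * (eBar - 0.5))
  ctxIndex <- function(amp, shift) {
    pre <- b + shift
    post <- b + shift + amp * kmPost
    (post - pre) / (post + pre)
  }
  eiFor <- function(sgn) {
    ra <- b + sgn * config$effectEngagement
    rp <- b
    (ra - rp) / (ra + rp)
  }
  eBar <- c(active = 1, passive = 0)
  shift <- function(sgn, ctx) sgn * config$effectEngagement * eBar[[ctx]]
  A <- config$effectSound
  P <- config$effectPhotostim
  out <- list()
  for (cls in c("Sound", "Photostim", "Sound&Photostim", "Unmodulated")) {
    sgn <- switch(cls, "Sound" = 1, "Photostim" = -1,
                  "Sound&Photostim" = 0, "Unmodulated" = -0.5)
    hasS <- cls %in% c("Sound", "Sound&Photostim")
    hasP <- cls %in% c("Photostim", "Sound&Photostim")
    smi <- vapply(c("active", "passive"), function(ctx) {
      ctxIndex(if (hasS) A * gainS(eBar[[ctx]]) else 0, shift(sgn, ctx))
    }, numeric(1))
    # PMI: post-window means, sound+stim vs sound-only (active context)
    sh <- shift(sgn, "active")
    rS <- b + sh + (if (hasS) A * gainS(1) else 0) * kmPost
    rSP <- rS + (if (hasP) P * gainP(1) else 0) * kmPost +
      (if (!hasP) config$crossTalk else 0) * kmPost
    pmi <- (rSP - rS) / (rSP + rS)
    # photostim response in spontaneous context, SMI form
    rPre <- b
    rPost <- b + (if (hasP) P else 0) * kmPost
    smiSpont <- (rPost - rPre) / (rPost + rPre)
    out[[cls]] <- c(smi_active = unname(smi[1]),
                    smi_passive = unname(smi[2]),
                    pmi = pmi, smi_spont = smiSpont, ei = eiFor(sgn))
  }
  out
}

#' Generate a complete synthetic session
#'
#' Builds a [PPCExperiment-class] whose activity is baseline plus
#' planted event-locked exponential transients plus i.i.d. Gaussian
#' noise. Sound-responsive neurons carry a positive engagement-linked
#' baseline shift in the active context; photostim-responsive and
#' unmodulated neurons carry a reduced baseline. Trial-to-trial
#' engagement states modulate response gains with the configured
#' couplings. The planted per-neuron functional classes and expected
#' index values are stored in `metadata(x)$ground_truth`, the planted
#' engagement direction (unit vector over neurons) in
#' `metadata(x)$engagement_direction`, and the per-trial engagement
#' states in `metadata(x)$trial_engagement`.
#'
#' @param config a [synthConfig()].
#' @return a [PPCExperiment-class]; seeded runs are bit-reproducible.
#' @examples
#' cfg <- synthConfig(nNeurons = c(Pyr = 30L, SOM = 4L, PV = 6L),
#'                    nTrials = c(active = 12L, passive = 10L,
#'                                spontaneous = 6L))
#' x <- generateSession(cfg)
#' table(groundTruth(x)$class)
#' @export
generateSession <- function(config) {
  withSeed(config$seed, {
    core <- .generateTrialsCore(config)
    tr <- core$trials
    e <- core$engagement
    fr <- config$frameRate
    n <- sum(config$nNeurons)
    nFrames <- core$nFrames

    cellType <- factor(rep(names(config$nNeurons), config$nNeurons),
                       levels = names(config$nNeurons))

    nSound <- as.integer(round(config$fracSound * n))
    nPhoto <- as.integer(round(config$fracPhotostim * n))
    nDual <- as.integer(round(config$fracDual * n))
    perm <- sample.int(n)
    cls <- rep("Unmodulated", n)
    cls[perm[seq_len(nSound)]] <- "Sound"
    cls[perm[nSound + seq_len(nPhoto)]] <- "Photostim"
    cls[perm[nSound + nPhoto + seq_len(nDual)]] <- "Sound&Photostim"
    cls <- factor(cls, levels = c("Sound", "Photostim",
                                  "Sound&Photostim", "Unmodulated"))
    prefSide <- rep(NA_character_, n)
    isSoundResp <- cls %in% c("Sound", "Sound&Photostim")
    isPhotoResp <- cls %in% c("Photostim", "Sound&Photostim")
    prefSide[isSoundResp] <- sample(c("left", "right"),
                                    sum(isSoundResp), replace = TRUE)

    eiSign <- c("Sound" = 1, "Photostim" = -1,
                "Sound&Photostim" = 0, "Unmodulated" = -0.5)[as.character(cls)]

    act <- matrix(rnorm(n * nFrames, sd = config$noiseSd), n, nFrames)
    act <- act + config$baseline

    kLen <- as.integer(ceiling(6 * config$decayS * fr))
    kernel <- exp(-(seq_len(kLen) - 1) / (config$decayS * fr))
    addTransient <- function(amp, at) {
      # amp: per-neuron amplitudes (0 allowed); at: onset frame
      len <- min(kLen, nFrames - at + 1L)
      if (len < 1L) return()
      nz <- which(amp != 0)
      if (!length(nz)) return()
      cols <- at:(at + len - 1L)
      act[nz, cols] <<- act[nz, cols] +
        outer(amp[nz], kernel[seq_len(len)])
    }

    soundAmpBase <- ifelse(isSoundResp, config$effectSound, 0)
    photoAmpBase <- ifelse(isPhotoResp, config$effectPhotostim, 0)

    for (i in seq_len(nrow(tr))) {
      ctx <- as.character(tr$context[i])
      if (ctx != "spontaneous") {
        et <- e[i]
        # engagement-linked baseline shift over the whole trial
        shift <- eiSign * config$effectEngagement * et
        cols <- tr$t_start[i]:tr$t_end[i]
        act[, cols] <- act[, cols] + shift
        gS <- max(0, 1 + config$coupleSound * (et - 0.5))
        gP <- max(0, 1 + config$couplePhotostim * (et - 0.5))
        sideGain <- ifelse(is.na(prefSide), 1,
                           ifelse(prefSide == tr$side[i], 1,
                                  1 - config$sideContrast))
        ampS <- soundAmpBase * sideGain * gS
        for (ev in c(tr$s1[i], tr$s2[i], tr$s3[i]))
          addTransient(ampS, ev)
        if (tr$photostim[i]) {
          addTransient(photoAmpBase * gP, tr$s1[i])
          if (config$crossTalk != 0)
            addTransient(ifelse(isSoundResp, config$crossTalk, 0),
                         tr$s1[i])
        }
      } else {
        addTransient(photoAmpBase, tr$s1[i])
      }
    }

    planted <- .plantedIndices(config)
    pl <- do.call(rbind, planted[as.character(cls)])
    gt <- DataFrame(class = cls, preferred_side = prefSide,
                    planted_smi_active = pl[, "smi_active"],
                    planted_smi_passive = pl[, "smi_passive"],
                    planted_pmi = pl[, "pmi"],
                    planted_smi_spont = pl[, "smi_spont"],
                    planted_ei = pl[, "ei"])

    dir <- eiSign * config$effectEngagement
    nrm <- sqrt(sum(dir^2))
    engDir <- if (nrm > 0) dir / nrm else dir

    PPCExperiment(act, cellType, tr, frameRate = fr,
                  metadata = list(ground_truth = gt,
                                  engagement_direction = engDir,
                                  trial_engagement = e,
                                  synth_config = config))
  })
}

#' Summarize the planted ground truth of a synthetic session
#'
#' @param gt the `ground_truth` DataFrame of a generated session (or a
#'   [PPCExperiment-class], from which it is extracted).
#' @return a data.frame with per-class neuron counts and mean planted
#'   index values.
#' @export
describeGroundTruth <- function(gt) {
  if (is(gt, "PPCExperiment")) gt <- groundTruth(gt)
  if (is.null(gt)) stop("no ground truth available")
  lev <- levels(gt$class)
  out <- data.frame(
    class = lev,
    n = as.integer(table(gt$class)[lev]),
    planted_smi_active = NA_real_, planted_smi_passive = NA_real_,
    planted_pmi = NA_real_, planted_ei = NA_real_
  )
  for (k in seq_along(lev)) {
    sel <- gt$class == lev[k]
    if (any(sel)) {
      out$planted_smi_active[k] <- mean(gt$planted_smi_active[sel])
      out$planted_smi_passive[k] <- mean(gt$planted_smi_passive[sel])
      out$planted_pmi[k] <- mean(gt$planted_pmi[sel])
      out$planted_ei[k] <- mean(gt$planted_ei[sel])
    }
  }
  out
}
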