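# Stochastic excitatory-inhibitory network model: selective sound
# inputs to E1/E2/I1/I2, photostimulation to subsets of Enon/Inon,
# and context inputs that gate response gain in the engaged state.

.SUBPOPS <- c("E1", "E2", "Enon", "I1", "I2", "Inon")
.EPOPS <- c("E1", "E2", "Enon")
.IPOPS <- c("I1", "I2", "Inon")

#' Network model parameters
#'
#' Defaults define the 8000-neuron network: 2040 E1, 2040 E2, 2720
#' Enon, 360 I1, 360 I2, 480 Inon; membrane time constants 20 ms (E)
#' and 10 ms (I); resting potential -60 mV; synaptic time constant
#' 2 ms; baseline drive 5; rate transfer `30 / (1 + exp(-(V - Vrest -
#' 15)/3))` Hz; forward-Euler step 0.1 ms; 1500 ms trials with
#' stimulus onset at 1000 ms; sound input decaying with a 500 ms
#' constant (truncated at 500 ms), amplitudes 5 (preferred side) and
#' 4.25 (non-preferred); 100 ms photostimulation; connection weights
#' W(E<-I) = -2.6042, W(I<-E) = 5.5147, W(I<-I) = -7.8125 mV with
#' probabilities 0.1739, 0.029, 0.1333 and no E-to-E connections;
#' 2000 context targets with gamma(5, 1) strengths; photostimulation
#' of half of Enon and Inon with gamma(7, 1) strengths.
#'
#' Variants: `"segregated"` (context targets exclude photostimulation
#' targets), `"overlapping"` (context targets drawn from all neurons),
#' `"opponent"` (segregated targeting plus an opponent-inhibition
#' motif: p(E1->I1) = p(E2->I2) = 0.044 with weight 11 mV, and
#' p(I1->E2) = p(I2->E1) = 0.26 with weight -3.9 mV).
#'
#' `inputConvention` controls how external and synaptic drive enter
#' the membrane equation: `"raw"` (default) reads the drive as a
#' millivolt deflection (`tau_m dV/dt = -(V - Vrest) + I`);
#' `"times_tau"` multiplies the drive by the membrane time constant.
#' The default is the reading under which baseline rates sit in the
#' lower dynamic range of the sigmoid (about 1 Hz) and sound responses
#' reach a few hertz; see the package vignette.
#'
#' @param variant connectivity/targeting variant.
#' @param sizes named subpopulation sizes.
#' @param nTargets number of context-input targets.
#' @param inputConvention `"raw"` or `"times_tau"`.
#' @param synJumpOverTau if TRUE presynaptic spikes increment the
#'   synaptic current by `J / tau_syn` instead of `J`.
#' @param dt,trialMs,tOn Euler step, trial duration, onset (ms).
#' @param soundDurMs sound-input truncation (ms); `Inf` disables.
#' @param ... overrides for the remaining slots (`iBase`, `tauM`,
#'   `vRest`, `tauSyn`, `rateMax`, `sigOffset`, `sigSlope`,
#'   `soundTauMs`, `photoDurMs`, `soundAmpPreferred`,
#'   `soundAmpNonpreferred`, `contextShape`, `contextScale`,
#'   `photoShape`, `photoScale`, `preWindowMs`, `postWindowMs`).
#' @return a [NetworkParams-class].
#' @export
networkParams <- function(variant = c("segregated", "overlapping",
                                      "opponent"),
                          sizes = c(E1 = 2040L, E2 = 2040L,
                                    Enon = 2720L, I1 = 360L,
                                    I2 = 360L, Inon = 480L),
                          nTargets = 2000L,
                          inputConvention = c("raw", "times_tau"),
                          synJumpOverTau = FALSE,
                          dt = 0.1, trialMs = 1500, tOn = 1000,
                          soundDurMs = 500, ...) {
  variant <- match.arg(variant)
  inputConvention <- match.arg(inputConvention)
  W <- matrix(0, 6, 6, dimnames = list(.SUBPOPS, .SUBPOPS))
  P <- matrix(0, 6, 6, dimnames = list(.SUBPOPS, .SUBPOPS))
  W[.EPOPS, .IPOPS] <- -2.6042; P[.EPOPS, .IPOPS] <- 0.1739
  W[.IPOPS, .EPOPS] <- 5.5147;  P[.IPOPS, .EPOPS] <- 0.029
  W[.IPOPS, .IPOPS] <- -7.8125; P[.IPOPS, .IPOPS] <- 0.1333
  if (variant == "opponent") {
    P["I1", "E1"] <- P["I2", "E2"] <- 0.044
    W["I1", "E1"] <- W["I2", "E2"] <- 11
    P["E2", "I1"] <- P["E1", "I2"] <- 0.26
    W["E2", "I1"] <- W["E1", "I2"] <- -3.9
  }
  defaults <- list(
    tauM = c(E = 20, I = 10), vRest = -60, tauSyn = 2, iBase = 5,
    rateMax = 30, sigOffset = 15, sigSlope = 3,
    soundTauMs = 500, photoDurMs = 100,
    soundAmpPreferred = 5, soundAmpNonpreferred = 4.25,
    contextShape = 5, contextScale = 1,
    photoShape = 7, photoScale = 1,
    preWindowMs = 700, postWindowMs = 300
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  new("NetworkParams",
      sizes = setNames(as.integer(sizes), names(sizes)),
      tauM = defaults$tauM, vRest = defaults$vRest,
      tauSyn = defaults$tauSyn, iBase = defaults$iBase,
      W = W, P = P, rateMax = defaults$rateMax,
      sigOffset = defaults$sigOffset, sigSlope = defaults$sigSlope,
      dt = dt, trialMs = trialMs, tOn = tOn,
      soundTauMs = defaults$soundTauMs, soundDurMs = soundDurMs,
      photoDurMs = defaults$photoDurMs,
      soundAmpPreferred = defaults$soundAmpPreferred,
      soundAmpNonpreferred = defaults$soundAmpNonpreferred,
      nContextTargets = as.integer(nTargets),
      contextShape = defaults$contextShape,
      contextScale = defaults$contextScale,
      photoShape = defaults$photoShape,
      photoScale = defaults$photoScale,
      variant = variant, inputConvention = inputConvention,
      synJumpOverTau = synJumpOverTau,
      preWindowMs = defaults$preWindowMs,
      postWindowMs = defaults$postWindowMs)
}

#' Sigmoidal rate transfer function
#'
#' `r(V) = rateMax / (1 + exp(-(V - Vrest - offset) / slope))`.
#'
#' @param vm membrane potential(s), mV.
#' @param params a [NetworkParams-class].
#' @return firing rate(s), Hz, bounded in `[0, rateMax]`.
#' @export
transferRate <- function(vm, params = networkParams()) {
  params@rateMax /
    (1 + exp(-(vm - params@vRest - params@sigOffset) / params@sigSlope))
}

#' Build a network realization
#'
#' Draws the Bernoulli block connectivity (constant weight per block,
#' no self-connections, no E-to-E connections), the photostimulation
#' targets (half of Enon and half of Inon, gamma-distributed
#' strengths) and the context targets (gamma-distributed strengths;
#' excluded from photostimulation targets unless the variant is
#' `"overlapping"`).
#'
#' @param params a [NetworkParams-class].
#' @param seed structural seed: the same seed reproduces connectivity
#'   and assignments exactly.
#' @return a [NetworkRealization-class].
#' @export
buildNetwork <- function(params = networkParams(), seed = 1L) {
  validObject(params)
  withSeed(seed, {
    sizes <- params@sizes
    n <- sum(sizes)
    subpop <- factor(rep(names(sizes), sizes), levels = .SUBPOPS)
    idx <- split(seq_len(n), subpop)

    ti <- tj <- tx <- vector("list", 36L)
    k <- 0L
    for (a in .SUBPOPS) for (b in .SUBPOPS) {
      p <- params@P[a, b]; w <- params@W[a, b]
      if (p <= 0 || w == 0) next
      na <- length(idx[[a]]); nb <- length(idx[[b]])
      hit <- which(runif(na * nb) < p)
      if (!length(hit)) next
      ii <- idx[[a]][((hit - 1L) %% na) + 1L]
      jj <- idx[[b]][((hit - 1L) %/% na) + 1L]
      keep <- ii != jj
      k <- k + 1L
      ti[[k]] <- ii[keep]; tj[[k]] <- jj[keep]
      tx[[k]] <- rep(w, sum(keep))
    }
    J <- sparseMatrix(i = as.integer(unlist(ti)),
                      j = as.integer(unlist(tj)),
                      x = as.numeric(unlist(tx)), dims = c(n, n))

    photo <- c(sample(idx$Enon, length(idx$Enon) %/% 2L),
               sample(idx$Inon, length(idx$Inon) %/% 2L))
    pool <- if (params@variant == "overlapping") seq_len(n)
    else setdiff(seq_len(n), photo)
    if (params@nContextTargets > length(pool))
      stop("not enough neurons outside the photostim targets")
    ctx <- sample(pool, params@nContextTargets)

    new("NetworkRealization", params = params,
        J = as(J, "CsparseMatrix"),
        subpop = subpop,
        contextTargets = sort(ctx),
        contextStrength = rgamma(length(ctx), shape = params@contextShape,
                                 scale = params@contextScale),
        photoTargets = sort(photo),
        photoStrength = rgamma(length(photo), shape = params@photoShape,
                               scale = params@photoScale),
        seed = as.integer(seed))
  })
}

# per-neuron static drive and stimulus amplitudes for one condition
.conditionInputs <- function(net, context, photostim, side) {
  p <- net@params
  n <- length(net@subpop)
  iBase <- rep(p@iBase, n)
  if (context == "active")
    iBase[net@contextTargets] <- iBase[net@contextTargets] +
      net@contextStrength
  ampSound <- numeric(n)
  pref <- if (side == "left") c("E1", "I1") else c("E2", "I2")
  nonpref <- if (side == "left") c("E2", "I2") else c("E1", "I1")
  ampSound[net@subpop %in% pref] <- p@soundAmpPreferred
  ampSound[net@subpop %in% nonpref] <- p@soundAmpNonpreferred
  ampPhoto <- numeric(n)
  if (photostim) ampPhoto[net@photoTargets] <- net@photoStrength
  list(iBase = iBase, ampSound = ampSound, ampPhoto = ampPhoto)
}

#' External input time course
#'
#' The per-neuron external drive at time `t` for a given condition:
#' baseline, plus the context term (active context, targeted neurons),
#' plus the exponentially decaying sound term (preferred /
#' non-preferred amplitude by side; zero for Enon and Inon), plus the
#' photostimulation boxcar (photostimulation trials, targeted
#' neurons). Used as the reference definition; the simulator applies
#' the identical time course.
#'
#' @param net a [NetworkRealization-class].
#' @param t time within the trial, ms.
#' @param context `"active"` or `"passive"`.
#' @param photostim logical: photostimulation trial.
#' @param side `"left"` or `"right"`.
#' @return per-neuron input vector.
#' @export
externalInput <- function(net, t, context = c("passive", "active"),
                          photostim = FALSE,
                          side = c("left", "right")) {
  context <- match.arg(context)
  side <- match.arg(side)
  p <- net@params
  ci <- .conditionInputs(net, context, photostim, side)
  soundF <- if (t >= p@tOn && t < p@tOn + p@soundDurMs)
    exp(-(t - p@tOn) / p@soundTauMs) else 0
  photoF <- as.numeric(t >= p@tOn && t <= p@tOn + p@photoDurMs)
  ci$iBase + ci$ampSound * soundF + ci$ampPhoto * photoF
}

#' Simulate trials of one condition
#'
#' Forward-Euler integration of the membrane and synaptic equations
#' with Bernoulli spiking (per-step probability `r(V) * dt`), for
#' `nTrials` independent trials of one stimulus-context-side
#' condition. Returns trial-averaged per-neuron rates in the
#' pre-onset and post-onset analysis windows, and per-subpopulation
#' rate traces.
#'
#' @param net a [NetworkRealization-class].
#' @param condition `"sound"` or `"sound+stim"`.
#' @param context `"active"` or `"passive"`.
#' @param side `"left"` or `"right"`.
#' @param nTrials trials to simulate.
#' @param seed trial-noise seed.
#' @param traceBinMs bin width for the returned subpopulation rate
#'   traces (0 disables).
#' @return list with `pre`, `post` (per-neuron mean rates, Hz),
#'   `trace` (subpopulations x bins), `maxRate`.
#' @export
simulateTrials <- function(net, condition = c("sound", "sound+stim"),
                           context = c("passive", "active"),
                           side = c("left", "right"),
                           nTrials = 10L, seed = 1L,
                           traceBinMs = 10) {
  condition <- match.arg(condition)
  context <- match.arg(context)
  side <- match.arg(side)
  p <- net@params
  ci <- .conditionInputs(net, context, condition == "sound+stim", side)
  tauM <- ifelse(net@subpop %in% .EPOPS, p@tauM[["E"]], p@tauM[["I"]])
  scale <- if (p@inputConvention == "times_tau") tauM
  else rep(1, length(tauM))
  out <- cpp_simulate_condition(
    net@J@p, net@J@i, net@J@x,
    tauM, scale, ci$iBase, ci$ampSound, ci$ampPhoto,
    p@vRest, p@tauSyn, p@dt, p@rateMax, p@sigOffset, p@sigSlope,
    p@trialMs, p@tOn, p@soundTauMs,
    if (is.finite(p@soundDurMs)) p@soundDurMs else p@trialMs,
    p@photoDurMs,
    p@tOn - p@preWindowMs, p@tOn,
    p@tOn, p@tOn + p@postWindowMs,
    as.integer(nTrials), as.double(seed),
    as.integer(net@subpop), nlevels(net@subpop), traceBinMs,
    p@synJumpOverTau)
  rownames(out$trace) <- levels(net@subpop)
  out
}

# condition grid used by runExperiment; seeds depend on stimulus and
# side but NOT on context, so zeroed context strengths make active
# and passive runs bitwise identical
.conditionSeed <- function(seed, condition, side) {
  as.numeric(seed) * 16 + 4 * (condition == "sound+stim") +
    2 * (side == "right") + 1
}

#' Run the full model experiment
#'
#' Simulates the sound-only and sound+photostimulation conditions in
#' the passive and active contexts over a fixed network realization,
#' and computes per-neuron model modulation indices: model SMI =
#' post-onset (300 ms) minus pre-onset (700 ms) trial-averaged rate
#' in the sound-only condition; model PMI = post-onset rate in the
#' sound+photostimulation condition minus the sound-only condition.
#' Both are rate differences in Hz (not normalized contrasts).
#' Population summaries report the mean absolute index over all
#' excitatory and all inhibitory neurons per context and the
#' active-minus-passive change.
#'
#' @param params a [NetworkParams-class], or a prebuilt
#'   [NetworkRealization-class].
#' @param nTrials trials per condition.
#' @param seed master seed (structural seed when `params` is a
#'   parameter set; trial seeds are derived per condition).
#' @param sides sound sides to simulate; with both, per-neuron indices
#'   are averaged across sides.
#' @param traceBinMs trace bin width (0 disables traces).
#' @return a [SimResult-class].
#' @export
runExperiment <- function(params = networkParams(), nTrials = 100L,
                          seed = 1L, sides = "left",
                          traceBinMs = 10) {
  net <- if (is(params, "NetworkRealization")) params
  else buildNetwork(params, seed = seed)
  p <- net@params
  if (nTrials < 1L) stop("nTrials must be at least 1")
  stopifnot(all(sides %in% c("left", "right")))

  runs <- list()
  for (cond in c("sound", "sound+stim")) for (ctx in c("passive", "active"))
    for (sd in sides) {
      key <- paste(cond, ctx, sd, sep = ".")
      runs[[key]] <- simulateTrials(
        net, cond, ctx, sd, nTrials = nTrials,
        seed = .conditionSeed(seed, cond, sd), traceBinMs = traceBinMs)
    }

  perSide <- function(ctx, sd) {
    s <- runs[[paste("sound", ctx, sd, sep = ".")]]
    sp <- runs[[paste("sound+stim", ctx, sd, sep = ".")]]
    list(smi = s$post - s$pre, pmi = sp$post - s$post)
  }
  avgSides <- function(ctx, what) {
    rowMeans(vapply(sides, function(sd) perSide(ctx, sd)[[what]],
                    numeric(length(net@subpop))))
  }
  isE <- net@subpop %in% .EPOPS
  ctxStrength <- photoStrength <- numeric(length(net@subpop))
  ctxStrength[net@contextTargets] <- net@contextStrength
  photoStrength[net@photoTargets] <- net@photoStrength
  index <- DataFrame(
    subpop = net@subpop,
    isE = isE,
    context_target = seq_along(net@subpop) %in% net@contextTargets,
    photo_target = seq_along(net@subpop) %in% net@photoTargets,
    context_strength = ctxStrength,
    photo_strength = photoStrength,
    smi_passive = avgSides("passive", "smi"),
    smi_active = avgSides("active", "smi"),
    pmi_passive = avgSides("passive", "pmi"),
    pmi_active = avgSides("active", "pmi")
  )
  summ <- do.call(rbind, lapply(c("smi", "pmi"), function(ix) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(e) {
      act <- mean(abs(index[[paste0(ix, "_active")]][index$isE == e]))
      pas <- mean(abs(index[[paste0(ix, "_passive")]][index$isE == e]))
      data.frame(index = toupper(ix),
                 population = if (e) "E" else "I",
                 mean_abs_passive = pas, mean_abs_active = act,
                 delta = act - pas)
    }))
  }))
  new("SimResult", params = p, index = index, summary = summ,
      traces = lapply(runs, function(r) r$trace),
      nTrials = as.integer(nTrials), sides = sides,
      seed = as.integer(seed),
      maxRate = max(vapply(runs, `[[`, numeric(1), "max_rate")))
}

#' @rdname accessors
#' @export
setMethod("modelDeltas", "SimResult", function(x) {
  s <- x@summary
  setNames(s$delta, paste0("d", s$index, "_", s$population))
})

#' Compare the model variants
#'
#' Runs the segregated, overlapping and opponent variants with shared
#' seeds and reports the active-minus-passive change in mean |SMI|
#' and |PMI| for the excitatory and inhibitory populations, plus the
#' sign of the photostimulation change (the overlapping variant
#' reverses it relative to the segregated network).
#'
#' @param nTrials trials per condition.
#' @param seed master seed (shared across variants).
#' @param variants variants to run.
#' @param params optional base [NetworkParams-class] whose scale
#'   settings (sizes, dt, trial structure) are reused for every
#'   variant.
#' @return data.frame, one row per variant, with columns `dSMI_E`,
#'   `dSMI_I`, `dPMI_E`, `dPMI_I` and `pmi_sign`.
#' @export
compareVariants <- function(nTrials = 100L, seed = 1L,
                            variants = c("segregated", "overlapping",
                                         "opponent"),
                            params = NULL) {
  rows <- lapply(variants, function(v) {
    pv <- if (is.null(params)) networkParams(variant = v)
    else networkParams(
      variant = v, sizes = params@sizes,
      nTargets = params@nContextTargets,
      inputConvention = params@inputConvention,
      synJumpOverTau = params@synJumpOverTau,
      dt = params@dt, trialMs = params@trialMs, tOn = params@tOn,
      soundDurMs = params@soundDurMs)
    sim <- runExperiment(pv, nTrials = nTrials, seed = seed,
                         traceBinMs = 0)
    d <- modelDeltas(sim)
    data.frame(variant = v, dSMI_E = d[["dSMI_E"]],
               dSMI_I = d[["dSMI_I"]], dPMI_E = d[["dPMI_E"]],
               dPMI_I = d[["dPMI_I"]],
               pmi_sign = sign(d[["dPMI_E"]]))
  })
  do.call(rbind, rows)
}
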