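#' Trial-structured calcium-imaging session
#'
#' `PPCExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' to hold a single imaging session: a neurons-by-frames activity matrix
#' (assay `"activity"`, typically dF/F), per-neuron cell-type labels in
#' `rowData()$cell_type`, the acquisition frame rate, and a trial table
#' with per-trial context, sound side, photostimulation flag, choice,
#' outcome, and event frame indices. Sessions produced by
#' [generateSession()] additionally carry the planted ground truth in
#' `metadata(x)$ground_truth`.
#'
#' The trial table has one row per trial (or per photostimulation event
#' in the spontaneous context) with columns `context` (active/passive/
#' spontaneous), `side`, `photostim`, `choice`, `correct`, and frame
#' indices `t_start`, `s1`, `s2`, `s3`, `turn`, `reward`, `t_end`; `s1`
#' is the alignment event (first sound onset, or photostimulation onset
#' in the spontaneous context).
#'
#' @slot trials a [S4Vectors::DataFrame] of trial metadata.
#' @slot frameRate acquisition rate in Hz.
#'
#' @aliases PPCExperiment
#' @export
setClass("PPCExperiment",
  contains = "SummarizedExperiment",
  slots = c(trials = "DFrame", frameRate = "numeric")
)

.validPPCExperiment <- function(object) {
  msg <- NULL
  if (!"activity" %in% names(assays(object)))
    msg <- c(msg, "assay 'activity' is required")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!"cell_type" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'cell_type'")
  tr <- object@trials
  need <- c("context", "side", "photostim", "t_start", "s1", "t_end")
  miss <- setdiff(need, colnames(tr))
  if (length(miss))
    msg <- c(msg, paste0("trials is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (nrow(tr) && all(c("t_start", "t_end") %in% colnames(tr))) {
    if (any(tr$t_end > ncol(object)))
      msg <- c(msg, "trial frames extend past the recording")
    if (any(tr$t_start < 1L))
      msg <- c(msg, "trial frames must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("PPCExperiment", .validPPCExperiment)

#' Construct a PPCExperiment
#'
#' @param activity numeric matrix, neurons x frames.
#' @param cellType character or factor of cell-type labels
#'   (one per neuron), e.g. `"Pyr"`, `"SOM"`, `"PV"`.
#' @param trials trial table (data.frame or DataFrame); see
#'   [PPCExperiment-class].
#' @param frameRate acquisition rate, Hz.
#' @param metadata optional named list stored in `metadata()`.
#' @return a [PPCExperiment-class] object.
#' @examples
#' act <- matrix(rnorm(40), nrow = 4)
#' tr <- data.frame(context = "active", side = "left", photostim = FALSE,
#'                  choice = "left", correct = TRUE,
#'                  t_start = 1L, s1 = 3L, s2 = 5L, s3 = 7L,
#'                  turn = 8L, reward = 9L, t_end = 10L)
#' PPCExperiment(act, rep(c("Pyr", "PV"), 2), tr, frameRate = 30)
#' @export
PPCExperiment <- function(activity, cellType, trials, frameRate = 30,
                          metadata = list()) {
  activity <- as.matrix(activity)
  if (length(cellType) != nrow(activity))
    stop("cellType must have one label per neuron (row of activity)")
  if (is.null(rownames(activity)))
    rownames(activity) <- sprintf("n%04d", seq_len(nrow(activity)))
  se <- SummarizedExperiment(
    assays = list(activity = activity),
    rowData = DataFrame(cell_type = as.factor(cellType)),
    metadata = metadata
  )
  new("PPCExperiment", se,
      trials = as(trials, "DFrame"),
      frameRate = as.numeric(frameRate))
}

#' Population-activity axis
#'
#' An L2-normalized weight vector over neurons defining a coding
#' direction (engagement, sound, or photostimulation axis), together
#' with the cross-validation bookkeeping of the fold that produced it.
#'
#' @slot weights numeric vector, one weight per neuron; unit L2 norm.
#' @slot axisKind one of `"engagement"`, `"sound"`, `"photostim"`.
#' @slot foldId integer fold index (NA outside cross-validation).
#' @slot trainingTrials integer indices of the trials used for the fit.
#' @export
setClass("AxisModel",
  slots = c(weights = "numeric", axisKind = "character",
            foldId = "integer", trainingTrials = "integer")
)

setValidity("AxisModel", function(object) {
  msg <- NULL
  nrm <- sqrt(sum(object@weights^2))
  if (abs(nrm - 1) > 1e-9)
    msg <- c(msg, "axis weights must have unit L2 norm")
  if (!object@axisKind %in% c("engagement", "sound", "photostim"))
    msg <- c(msg, "axisKind must be engagement, sound or photostim")
  if (is.null(msg)) TRUE else msg
})

#' Parameterization of the excitatory-inhibitory network model
#'
#' Holds the full parameter set of the stochastic E-I spiking network:
#' subpopulation sizes, membrane and synaptic time constants, the
#' block-level synaptic weights and connection probabilities, the
#' sigmoidal transfer function, stimulus time courses, and the
#' context/photostimulation input assignments. See [networkParams()].
#'
#' @export
setClass("NetworkParams",
  slots = c(
    sizes = "integer",          # named: E1,E2,Enon,I1,I2,Inon
    tauM = "numeric",           # named: E, I (ms)
    vRest = "numeric",          # mV
    tauSyn = "numeric",         # ms
    iBase = "numeric",          # baseline external drive
    W = "matrix",               # 6x6 subpopulation weights [post, pre], mV
    P = "matrix",               # 6x6 connection probabilities [post, pre]
    rateMax = "numeric",        # Hz
    sigOffset = "numeric",      # mV above rest at half-maximum
    sigSlope = "numeric",       # mV
    dt = "numeric",             # ms
    trialMs = "numeric",
    tOn = "numeric",            # stimulus onset, ms
    soundTauMs = "numeric",     # sound input decay constant
    soundDurMs = "numeric",     # sound input truncation
    photoDurMs = "numeric",
    soundAmpPreferred = "numeric",
    soundAmpNonpreferred = "numeric",
    nContextTargets = "integer",
    contextShape = "numeric", contextScale = "numeric",
    photoShape = "numeric", photoScale = "numeric",
    variant = "character",      # segregated / overlapping / opponent
    inputConvention = "character", # raw / times_tau
    synJumpOverTau = "logical",
    preWindowMs = "numeric",    # SMI pre window length
    postWindowMs = "numeric"    # SMI/PMI post window length
  )
)

setValidity("NetworkParams", function(object) {
  msg <- NULL
  nm <- c("E1", "E2", "Enon", "I1", "I2", "Inon")
  if (!identical(names(object@sizes), nm))
    msg <- c(msg, "sizes must be named E1,E2,Enon,I1,I2,Inon")
  if (any(object@sizes <= 0L))
    msg <- c(msg, "all subpopulation sizes must be positive")
  if (any(object@P < 0 | object@P > 1))
    msg <- c(msg, "connection probabilities must lie in [0, 1]")
  if (any(object@P[1:3, 1:3] != 0))
    msg <- c(msg, "excitatory-to-excitatory connections must be absent")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@tOn + object@postWindowMs > object@trialMs)
    msg <- c(msg, "post-onset window extends past the trial")
  if (object@nContextTargets > sum(object@sizes))
    msg <- c(msg, "more context targets than neurons")
  if (!object@variant %in% c("segregated", "overlapping", "opponent"))
    msg <- c(msg, "unknown variant")
  if (!object@inputConvention %in% c("raw", "times_tau"))
    msg <- c(msg, "inputConvention must be 'raw' or 'times_tau'")
  if (is.null(msg)) TRUE else msg
})

#' A realized network: connectivity and input assignments
#'
#' Produced by [buildNetwork()]. Connectivity is a sparse post-by-pre
#' weight matrix with zero diagonal and no E-to-E entries; context and
#' photostimulation input targets are index vectors with per-neuron
#' gamma-distributed strengths.
#'
#' @export
setClass("NetworkRealization",
  slots = c(
    params = "NetworkParams",
    J = "dgCMatrix",
    subpop = "factor",
    contextTargets = "integer",
    contextStrength = "numeric",
    photoTargets = "integer",
    photoStrength = "numeric",
    seed = "integer"
  )
)

setValidity("NetworkRealization", function(object) {
  msg <- NULL
  if (any(Matrix::diag(object@J) != 0))
    msg <- c(msg, "self-connections are not allowed")
  if (length(object@contextTargets) != length(object@contextStrength))
    msg <- c(msg, "context strengths misaligned with targets")
  if (length(object@photoTargets) != length(object@photoStrength))
    msg <- c(msg, "photostim strengths misaligned with targets")
  if (object@params@variant != "overlapping" &&
      length(intersect(object@contextTargets, object@photoTargets)))
    msg <- c(msg, "context and photostim targets must be disjoint")
  if (is.null(msg)) TRUE else msg
})

#' Simulation result of the network model
#'
#' Per-neuron trial-averaged window rates and model modulation indices
#' (rate differences, in Hz) for each context, plus population
#' summaries. Model SMI is the post-onset minus pre-onset rate in the
#' sound-only condition; model PMI is the post-onset rate in the
#' sound+photostimulation condition minus that in the sound-only
#' condition. See [runExperiment()].
#'
#' @export
setClass("SimResult",
  slots = c(
    params = "NetworkParams",
    index = "DFrame",        # per neuron: subpop, isE, smi/pmi per context
    summary = "data.frame",  # population x context means of |SMI|, |PMI|
    traces = "list",         # per condition: subpop x time-bin mean rates
    nTrials = "integer",
    sides = "character",
    seed = "integer",
    maxRate = "numeric"
  )
)
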