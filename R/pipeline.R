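# Pipeline orchestration: synthetic session -> modulation -> axes ->
# decoding, with a run manifest, plus the variant-comparison
# validation table for the network model.

#' Pipeline configuration
#'
#' @param synth a [synthConfig()].
#' @param windows a [windowSpec()].
#' @param decode a [decodeSpec()].
#' @param network a [NetworkParams-class] (used when the `network`
#'   stage is enabled).
#' @param stages character vector of stages to run, in order, from
#'   `"synth"`, `"modulation"`, `"axes"`, `"decoding"`, `"network"`.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param outDir optional output directory for CSV summaries and the
#'   manifest.
#' @param nShuffles shuffles for modulation significance.
#' @param networkTrials trials per condition for the network stage.
#' @return a list of class `ppc_pipeline_config`.
#' @export
pipelineConfig <- function(synth = synthConfig(),
                           windows = windowSpec(),
                           decode = decodeSpec(),
                           network = networkParams(),
                           stages = c("synth", "modulation", "axes",
                                      "decoding"),
                           seed = 1L, outDir = NULL,
                           nShuffles = 1000L, networkTrials = 50L) {
  known <- c("synth", "modulation", "axes", "decoding", "network")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(synth = synth, windows = windows, decode = decode,
                 network = network, stages = stages,
                 seed = as.integer(seed), outDir = outDir,
                 nShuffles = as.integer(nShuffles),
                 networkTrials = as.integer(networkTrials)),
            class = "ppc_pipeline_config")
}

# compact numeric fingerprint for the manifest (dims + moments)
.fingerprint <- function(m) {
  m <- as.matrix(m)
  list(dim = dim(m), mean = mean(m, na.rm = TRUE),
       sd = sd(as.numeric(m), na.rm = TRUE))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic session (or a
#' supplied one), collecting per-stage results and a JSON-serializable
#' manifest (package version, seeds, stage status and timings, input
#' fingerprints). A failing stage aborts with the stage name. When
#' `outDir` is set, stage summaries are written as CSV and the
#' manifest as JSON.
#'
#' @param config a [pipelineConfig()].
#' @param session optional existing [PPCExperiment-class]; required
#'   if the `synth` stage is disabled but analysis stages are enabled.
#' @return list with `manifest` and `results` (one element per stage).
#' @export
runPipeline <- function(config = pipelineConfig(), session = NULL) {
  stopifnot(inherits(config, "ppc_pipeline_config"))
  manifest <- list(package = "ppcgate",
                   version = as.character(packageVersion("ppcgate")),
                   seed = config$seed, stages = list())
  results <- list()
  stageSeed <- function(k) config$seed + 1000L * k

  runStage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    out
  }

  if ("synth" %in% config$stages) {
    session <- runStage("synth", function() {
      cfg <- config$synth
      cfg$seed <- stageSeed(1L)
      generateSession(cfg)
    })
    manifest$input <- .fingerprint(activity(session))
    results$synth <- describeGroundTruth(session)
  } else if (!is.null(session)) {
    manifest$input <- .fingerprint(activity(session))
  }

  needs <- intersect(config$stages,
                     c("modulation", "axes", "decoding"))
  if (length(needs) && is.null(session))
    stop(sprintf("stage '%s' requires a session: enable 'synth' or %s",
                 needs[1], "pass one via the session argument"))

  if ("modulation" %in% config$stages) {
    results$modulation <- runStage("modulation", function()
      computeModulation(session, windows = config$windows,
                        nShuffles = config$nShuffles,
                        seed = stageSeed(2L)))
  }

  if ("axes" %in% config$stages) {
    results$axes <- runStage("axes", function() {
      eng <- crossvalProject(session, "engagement",
                             windows = config$windows,
                             seed = stageSeed(3L))
      snd <- crossvalProject(session, "sound",
                             windows = config$windows,
                             seed = stageSeed(3L))
      coup <- engagementResponseCoupling(eng$trials$pre,
                                         snd$trials$post)
      act <- eng$trials$context == "active"
      tr <- trials(session)
      ep <- eng$trials$pre[act]
      epc <- (ep - mean(ep)) / sd(ep) # center for the default bins
      perf <- performanceByEngagement(
        epc, tr$correct[eng$trials$trial[act]])
      list(engagement = eng, sound = snd, coupling = coup,
           performance = perf)
    })
  }

  if ("decoding" %in% config$stages) {
    results$decoding <- runStage("decoding", function() {
      tr <- trials(session)
      rows <- which(tr$context == "active")
      bal <- balanceTrials(tr, "side", "choice",
                           minPerCell = config$decode$minTrialsPerCondition,
                           nRepeats = 1L, seed = stageSeed(4L),
                           trialRows = rows)
      if (bal$excluded)
        stop("insufficient trials per condition for decoding")
      al <- alignTruncate(session, trialRows = bal$repeats[[1]])
      decodePopulation(al$tensor, tr$side[al$trialRows],
                       spec = config$decode,
                       frameRate = frameRate(session),
                       eventIndex = al$eventIndex,
                       seed = stageSeed(5L))
    })
  }

  if ("network" %in% config$stages) {
    results$network <- runStage("network", function()
      runExperiment(config$network, nTrials = config$networkTrials,
                    seed = stageSeed(6L), traceBinMs = 0))
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(results$modulation))
      writeModulation(results$modulation,
                      file.path(config$outDir, "modulation.csv"))
    if (!is.null(results$synth))
      write.csv(results$synth,
                file.path(config$outDir, "ground_truth_summary.csv"),
                row.names = FALSE)
    if (!is.null(results$network))
      write.csv(modelSummary(results$network),
                file.path(config$outDir, "network_summary.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, results = results)
}

#' Compare computed quantities against expected values
#'
#' Generic pass/fail table builder used to validate the
#' variant-comparison deltas (or any named numeric summary) against
#' expected values at a stated absolute tolerance.
#'
#' @param computed named numeric vector (e.g. [modelDeltas()] output,
#'   or a row of [compareVariants()]).
#' @param expected named numeric vector of reference values (names
#'   must match `computed`).
#' @param tolerance absolute tolerance (scalar or per-entry).
#' @return data.frame with columns quantity, computed, expected,
#'   tolerance, pass.
#' @export
validateAcceptance <- function(computed, expected, tolerance = 0.05) {
  nm <- names(expected)
  if (is.null(nm) || !all(nm %in% names(computed)))
    stop("expected values must be named and present in computed")
  tolerance <- rep_len(tolerance, length(nm))
  data.frame(
    quantity = nm,
    computed = as.numeric(computed[nm]),
    expected = as.numeric(expected),
    tolerance = tolerance,
    pass = abs(as.numeric(computed[nm]) - as.numeric(expected)) <=
      tolerance
  )
}
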