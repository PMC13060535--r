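# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small session: quick, used by most analysis tests
smallSession <- function() {
  memo("small", generateSession(synthConfig(
    nNeurons = c(Pyr = 40L, SOM = 5L, PV = 8L),
    nTrials = c(active = 40L, passive = 30L, spontaneous = 12L),
    noiseSd = 0.08, seed = 3L)))
}

smallModulation <- function() {
  memo("small_mod",
       computeModulation(smallSession(), nShuffles = 300, seed = 11L))
}

# hand-built experiment with exactly controlled trial timing
manualExperiment <- function(segA = 12L, segB = c(10L, 11L, 12L)) {
  nTr <- length(segB)
  t_start <- s1 <- s2 <- s3 <- turn <- reward <- t_end <- integer(nTr)
  cursor <- 1L
  for (i in seq_len(nTr)) {
    t_start[i] <- cursor
    s1[i] <- cursor + segA
    s2[i] <- s1[i] + 5L
    s3[i] <- s2[i] + 5L
    turn[i] <- s3[i] + segB[i]
    reward[i] <- turn[i] + 4L
    t_end[i] <- reward[i] + 6L
    cursor <- t_end[i] + 1L
  }
  tr <- data.frame(context = "active",
                   side = rep(c("left", "right"), length.out = nTr),
                   photostim = FALSE,
                   choice = "left", correct = TRUE,
                   t_start = t_start, s1 = s1, s2 = s2, s3 = s3,
                   turn = turn, reward = reward, t_end = t_end)
  n <- 3L
  act <- matrix(seq_len(n * max(t_end)) / 100, nrow = n)
  PPCExperiment(act, c("Pyr", "SOM", "PV"), tr, frameRate = 30)
}

# full-size network simulations shared between acceptance criteria and
# property tests; built once per variant
variantSim <- function(variant, nTrials = 20L, seed = 42L) {
  memo(paste0("sim_", variant, "_", nTrials, "_", seed),
       runExperiment(networkParams(variant = variant),
                     nTrials = nTrials, seed = seed, traceBinMs = 50))
}

# small network for fast structural/property checks
smallNet <- function(variant = "segregated", seed = 7L) {
  memo(paste0("net_", variant, "_", seed), {
    buildNetwork(networkParams(
      variant = variant,
      sizes = c(E1 = 255L, E2 = 255L, Enon = 340L,
                I1 = 45L, I2 = 45L, Inon = 60L),
      nTargets = 250L), seed = seed)
  })
}
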