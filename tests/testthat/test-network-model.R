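test_that("parameter container enforces model invariants", {
  p <- networkParams()
  expect_equal(sum(p@sizes), 8000L)
  expect_equal(sum(p@sizes[c("E1", "E2", "Enon")]), 6800L)
  expect_equal(sum(p@sizes[c("I1", "I2", "Inon")]), 1200L)
  expect_equal(unname(p@W["E1", "I1"]), -2.6042)
  expect_equal(unname(p@P["I1", "E2"]), 0.029)
  expect_error(networkParams(bogus = 1), "unknown")

  po <- networkParams("opponent")
  expect_equal(unname(po@P["I1", "E1"]), 0.044)
  expect_equal(unname(po@W["E2", "I1"]), -3.9)
  expect_equal(unname(po@P["E1", "I2"]), 0.26)
  # non-motif blocks keep the default values
  expect_equal(unname(po@P["I1", "E2"]), 0.029)
})

test_that("realized connectivity follows the Bernoulli block model", {
  net <- smallNet()
  J <- net@J
  sub <- net@subpop
  isE <- sub %in% c("E1", "E2", "Enon")

  expect_true(all(Matrix::diag(J) == 0))
  # no connections between excitatory neurons
  expect_equal(sum(J[isE, isE] != 0), 0)

  # realized densities within 4 sigma of the binomial expectation
  checkBlock <- function(postSel, preSel, p, w) {
    nPairs <- sum(postSel) * sum(preSel)
    k <- sum(J[postSel, preSel] != 0)
    expect_lt(abs(k - nPairs * p), 4 * sqrt(nPairs * p * (1 - p)) + 1)
    expect_true(all(J[postSel, preSel]@x == w))
  }
  checkBlock(isE, !isE, 0.1739, -2.6042)
  checkBlock(!isE, isE, 0.029, 5.5147)
  checkBlock(!isE & sub != "Inon", !isE, 0.1333, -7.8125)

  # segregated targeting: disjoint context and photostim targets
  expect_length(intersect(net@contextTargets, net@photoTargets), 0)
  # photostim covers half of Enon and half of Inon
  expect_equal(length(net@photoTargets),
               sum(net@params@sizes[c("Enon", "Inon")] %/% 2L))

  # structural determinism
  net2 <- buildNetwork(net@params, seed = net@seed)
  expect_identical(net@J@x, net2@J@x)
  expect_identical(net@contextTargets, net2@contextTargets)
})

test_that("rate transfer function", {
  p <- networkParams()
  expect_equal(transferRate(-60 + 15, p), 15)
  expect_equal(transferRate(1e3, p), 30)
  expect_equal(transferRate(-60, p), 30 / (1 + exp(5)),
               tolerance = 1e-6)
  expect_equal(transferRate(-60, p), 0.2007, tolerance = 1e-3)
})

test_that("external input composes baseline, context, sound, photostim", {
  net <- smallNet()
  p <- net@params
  # passive, pre-onset: baseline only
  expect_equal(externalInput(net, 500, "passive"), rep(5, 1000))
  # at onset: preferred populations get the full sound amplitude
  ii <- externalInput(net, p@tOn, "passive", photostim = FALSE,
                      side = "left")
  e1 <- net@subpop == "E1"
  e2 <- net@subpop == "E2"
  expect_true(all(ii[e1] == 5 + 5))
  expect_true(all(ii[e2] == 5 + 4.25))
  # no sound or photostim to non-selective neurons off the mask
  enonFree <- setdiff(which(net@subpop == "Enon"), net@photoTargets)
  iOn <- externalInput(net, p@tOn + 50, "passive", photostim = TRUE,
                       side = "left")
  expect_true(all(iOn[enonFree] == 5))
  # context adds gamma strengths for targeted neurons in active only
  iAct <- externalInput(net, 500, "active")
  expect_equal(iAct[net@contextTargets] - 5, net@contextStrength)
  # sound input decays exponentially and is truncated
  i300 <- externalInput(net, p@tOn + 300, "passive", side = "left")
  expect_equal(unname(i300[which(e1)[1]] - 5), 5 * exp(-300 / 500),
               tolerance = 1e-12)
  i600 <- externalInput(net, p@tOn + 600, "passive", side = "left")
  expect_true(all(i600 == 5))
})

test_that("single-neuron dynamics reach the closed-form fixed point", {
  # unconnected network: V* = Vrest + I (raw) or Vrest + tau*I
  for (conv in c("raw", "times_tau")) {
    p <- networkParams(
      sizes = c(E1 = 4L, E2 = 4L, Enon = 4L, I1 = 2L, I2 = 2L,
                Inon = 2L),
      nTargets = 0L, inputConvention = conv, iBase = 0.5)
    p@P[] <- 0
    net <- buildNetwork(p, seed = 1)
    out <- simulateTrials(net, "sound", "passive", "left",
                          nTrials = 1, seed = 1, traceBinMs = 10)
    tauM <- c(20, 10)
    vStar <- -60 + 0.5 * (if (conv == "times_tau") tauM else c(1, 1))
    expected <- transferRate(vStar, p)
    # late pre-onset bins: settled to the fixed point within 1%
    eBins <- rowMeans(out$trace[c("E1", "I1"), 60:99])
    expect_equal(unname(eBins), expected, tolerance = 0.01)
  }
})

test_that("simulated rates respect the transfer bound", {
  net <- smallNet()
  out <- simulateTrials(net, "sound+stim", "active", "left",
                        nTrials = 2, seed = 3, traceBinMs = 10)
  expect_lte(out$max_rate, 30)
  expect_gte(min(out$trace), 0)
  # per-step spike probability bound
  expect_lte(out$max_rate * net@params@dt / 1000, 0.003)
  # population rates stationary before onset: last 500 ms of the
  # pre-onset period drifts by less than 5%
  pre1 <- mean(out$trace[, 51:75])
  pre2 <- mean(out$trace[, 76:100])
  expect_lt(abs(pre2 - pre1) / pre1, 0.05)
})

test_that("zero context input makes active and passive identical", {
  p <- networkParams(
    sizes = c(E1 = 102L, E2 = 102L, Enon = 136L, I1 = 18L, I2 = 18L,
              Inon = 24L), nTargets = 0L)
  net <- buildNetwork(p, seed = 5)
  a <- simulateTrials(net, "sound", "active", "left", nTrials = 2,
                      seed = 9, traceBinMs = 0)
  b <- simulateTrials(net, "sound", "passive", "left", nTrials = 2,
                      seed = 9, traceBinMs = 0)
  expect_identical(a$pre, b$pre)
  expect_identical(a$post, b$post)
})

test_that("experiment bookkeeping: determinism and summaries", {
  p <- networkParams(
    sizes = c(E1 = 102L, E2 = 102L, Enon = 136L, I1 = 18L, I2 = 18L,
              Inon = 24L), nTargets = 100L)
  s1 <- runExperiment(p, nTrials = 2, seed = 8, traceBinMs = 0)
  s2 <- runExperiment(p, nTrials = 2, seed = 8, traceBinMs = 0)
  expect_identical(s1@index$smi_active, s2@index$smi_active)
  expect_identical(modelDeltas(s1), modelDeltas(s2))
  expect_equal(nrow(modelSummary(s1)), 4L)
  expect_error(runExperiment(p, nTrials = 0), "at least 1")
})
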