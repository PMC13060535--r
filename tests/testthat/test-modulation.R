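test_that("contrast index arithmetic, symmetry and bounds", {
  expect_equal(modulationIndex(0.1, 0.3), 0.5)
  expect_equal(modulationIndex(0.2, 0.2), 0)
  expect_equal(modulationIndex(0, 0.2), 1)
  expect_equal(modulationIndex(0, 0), 0)
  expect_warning(bad <- modulationIndex(-0.3, 0.1), "denominator")
  expect_true(is.nan(bad))

  # antisymmetry and boundedness over random non-negative inputs
  set.seed(1)
  a <- runif(500); b <- runif(500)
  expect_equal(modulationIndex(a, b), -modulationIndex(b, a))
  expect_true(all(abs(modulationIndex(a, b)) <= 1))
})

test_that("larger-magnitude side is kept with sign preserved", {
  expect_equal(pickLargerSide(0.2, -0.6), -0.6)
  expect_equal(pickLargerSide(0.3, 0.3), 0.3)
  expect_equal(pickLargerSide(NA, 0.4), 0.4)
  expect_equal(pickLargerSide(c(0.2, -0.5), c(0.1, 0.1)), c(0.2, -0.5))
})

test_that("shuffle significance controls the null and detects effects", {
  # planted null: identical distributions, mostly "none"
  set.seed(6)
  calls <- vapply(1:120, function(k) {
    shuffleSignificance(rnorm(30, 1, 0.3), rnorm(30, 1, 0.3),
                        nShuffles = 200, seed = k)$call
  }, character(1))
  expect_gte(mean(calls == "none"), 0.95)

  # magnitude-threshold rule: a tiny but reliable index stays "none"
  a <- rep(1.00, 60) + rnorm(60, sd = 1e-4)
  b <- rep(1.20, 60) + rnorm(60, sd = 1e-4) # index ~ 0.09 < 0.1
  res <- shuffleSignificance(a, b, nShuffles = 500, seed = 2)
  expect_lt(res$index, 0.1)
  expect_identical(res$call, "none")

  # strong planted effect: called positive almost always
  hits <- vapply(1:40, function(k) {
    withr::with_seed(k, {
      a <- abs(rnorm(50, 0.1, 0.02))
      b <- abs(rnorm(50, 0.4, 0.05)) # index ~ 0.6
    })
    shuffleSignificance(a, b, nShuffles = 300, seed = k)$call
  }, character(1))
  expect_gt(mean(hits == "positive"), 0.95)
})

test_that("functional classification follows the significance flags", {
  expect_equal(as.character(classifyFunctional(TRUE, FALSE)), "Sound")
  expect_equal(as.character(classifyFunctional(FALSE, TRUE)),
               "Photostim")
  expect_equal(as.character(classifyFunctional(TRUE, TRUE)),
               "Sound&Photostim")
  expect_equal(as.character(classifyFunctional(FALSE, FALSE)),
               "Unmodulated")
})

test_that("planted classes are recovered on a synthetic session", {
  x <- smallSession()
  mod <- smallModulation()
  gt <- groundTruth(x)

  # indices bounded for the synthetic (non-negative baseline) session
  expect_true(all(abs(mod$smi_active) <= 1, na.rm = TRUE))
  expect_true(all(abs(mod$ei) <= 1, na.rm = TRUE))

  # per-class balanced accuracy
  conf <- table(truth = gt$class, called = mod$functional_class)
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  present <- rowSums(conf) > 0
  expect_gte(mean(recall[present]), 0.9)

  # recovered index magnitudes track the planted values
  sound <- gt$class == "Sound"
  expect_equal(mean(mod$smi_active[sound]),
               mean(gt$planted_smi_active[sound]), tolerance = 0.12)
})

test_that("deltaStim reflects the planted photostim response", {
  cfg <- synthConfig(
    nNeurons = c(Pyr = 20L, SOM = 2L, PV = 2L),
    nTrials = c(active = 80L, passive = 10L, spontaneous = 4L),
    fracSound = 0.3, fracPhotostim = 0.25, fracDual = 0,
    effectPhotostim = 0.2, effectEngagement = 0,
    coupleSound = 0, couplePhotostim = 0, noiseSd = 0.05,
    crossTalk = -0.1, seed = 41L)
  x <- generateSession(cfg)
  gt <- groundTruth(x)
  ds <- deltaStim(x, "active")
  km <- ppcgate:::kernelWindowMean(30, 30L)
  photo <- gt$class == "Photostim"
  sound <- gt$class == "Sound"
  expect_lt(abs(mean(ds[photo]) - 0.2 * km), 0.03)
  # planted cross-suppression shows up in sound-only neurons
  expect_lt(abs(mean(ds[sound]) - (-0.1 * km)), 0.03)
  # unmodulated neurons are unchanged
  expect_lt(abs(mean(ds[gt$class == "Unmodulated"])), 0.03)
})

test_that("modulation output is reproducible under a fixed seed", {
  x <- smallSession()
  m1 <- computeModulation(x, nShuffles = 100, seed = 9L)
  m2 <- computeModulation(x, nShuffles = 100, seed = 9L)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})
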