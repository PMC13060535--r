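test_that("trial table has the configured structure", {
  cfg <- synthConfig(nTrials = c(active = 90L, passive = 30L,
                                 spontaneous = 30L), seed = 2L)
  tr <- generateTrialTable(cfg)

  # photostim flagged on exactly a third of active trials
  act <- tr[tr$context == "active", ]
  expect_equal(sum(act$photostim), 30L)

  # event ordering holds in every active/passive trial
  ap <- tr[tr$context != "spontaneous", ]
  expect_true(all(ap$s1 < ap$s2 & ap$s2 < ap$s3 & ap$s3 < ap$turn &
                    ap$turn < ap$reward & ap$reward < ap$t_end))
  expect_true(all(ap$t_start < ap$s1))

  # spontaneous events at regular 10 s intervals: 30 events span 290 s
  sp <- tr[tr$context == "spontaneous", ]
  expect_equal(nrow(sp), 30L)
  expect_true(all(diff(sp$s1) == 10 * cfg$frameRate))
})

test_that("configuration errors are rejected", {
  expect_error(synthConfig(fracSound = 0.7, fracPhotostim = 0.3,
                           fracDual = 0.1), "sum")
  expect_error(synthConfig(nTrials = c(active = 0L, passive = 10L,
                                       spontaneous = 5L)), "positive")
  expect_error(synthConfig(frameRate = -1), "frameRate")
})

test_that("ground-truth classes partition the neurons", {
  x <- smallSession()
  gt <- groundTruth(x)
  expect_equal(length(gt$class), nrow(x))
  expect_false(anyNA(gt$class))
  d <- describeGroundTruth(x)
  expect_equal(sum(d$n), nrow(x))
  # engagement direction is a unit vector
  eng <- S4Vectors::metadata(x)$engagement_direction
  expect_equal(sqrt(sum(eng^2)), 1, tolerance = 1e-12)
})

test_that("seeded generation is bit-reproducible", {
  cfg <- synthConfig(nNeurons = c(Pyr = 10L, SOM = 2L, PV = 3L),
                     nTrials = c(active = 8L, passive = 6L,
                                 spontaneous = 4L), seed = 99L)
  x1 <- generateSession(cfg)
  x2 <- generateSession(cfg)
  expect_identical(activity(x1), activity(x2))
  expect_identical(as.data.frame(trials(x1)), as.data.frame(trials(x2)))
})

test_that("planted sound index is recovered at large trial counts", {
  target <- 0.5
  cfg <- synthConfig(
    nNeurons = c(Pyr = 24L, SOM = 3L, PV = 3L),
    nTrials = c(active = 220L, passive = 200L, spontaneous = 6L),
    fracSound = 0.5, fracPhotostim = 0, fracDual = 0,
    effectSound = amplitudeForIndex(target, 0.2),
    effectEngagement = 0, coupleSound = 0, couplePhotostim = 0,
    sideContrast = 0, noiseSd = 0.1, seed = 21L)
  x <- generateSession(cfg)
  gt <- groundTruth(x)
  expect_equal(unique(gt$planted_smi_active[gt$class == "Sound"]),
               target, tolerance = 1e-12)
  mod <- computeModulation(x, nShuffles = 100, seed = 4L)
  rec <- median(mod$smi_active[gt$class == "Sound"])
  expect_lt(abs(rec - target), 0.05)
})

test_that("increasing the sound effect increases recovered indices", {
  med <- vapply(c(0.1, 0.3, 0.6), function(eff) {
    cfg <- synthConfig(
      nNeurons = c(Pyr = 16L, SOM = 2L, PV = 2L),
      nTrials = c(active = 60L, passive = 10L, spontaneous = 4L),
      fracSound = 0.5, fracPhotostim = 0, fracDual = 0,
      effectSound = eff, effectEngagement = 0,
      coupleSound = 0, sideContrast = 0, seed = 31L)
    x <- generateSession(cfg)
    mod <- computeModulation(x, nShuffles = 50, seed = 5L)
    median(mod$smi_active[groundTruth(x)$class == "Sound"])
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("null effects give near-nominal significance rates", {
  # all planted effects zero: significant calls are false positives
  calls <- unlist(lapply(1:8, function(s) {
    cfg <- synthConfig(
      nNeurons = c(Pyr = 16L, SOM = 2L, PV = 2L),
      nTrials = c(active = 30L, passive = 30L, spontaneous = 8L),
      effectSound = 0, effectPhotostim = 0, effectEngagement = 0,
      coupleSound = 0, couplePhotostim = 0, crossTalk = 0,
      seed = 100L + s)
    x <- generateSession(cfg)
    mod <- computeModulation(x, nShuffles = 200, seed = 7L)
    c(mod$smi_active_call, mod$smi_passive_call, mod$smi_spont_call)
  }))
  fp <- mean(calls != "none")
  # the 0.1 magnitude threshold makes the 5% two-tailed test conservative
  expect_lt(fp, 0.05 + 2 * sqrt(0.05 * 0.95 / length(calls)))
})

test_that("session container round-trips through the text format", {
  cfg <- synthConfig(nNeurons = c(Pyr = 6L, SOM = 2L, PV = 2L),
                     nTrials = c(active = 5L, passive = 4L,
                                 spontaneous = 3L), seed = 12L)
  x <- generateSession(cfg)
  dir <- tempfile("session")
  writeSession(x, dir)
  y <- readSession(dir)
  expect_equal(activity(y), activity(x), tolerance = 1e-12)
  expect_equal(as.character(cellTypes(y)), as.character(cellTypes(x)))
  expect_equal(frameRate(y), frameRate(x))
  expect_equal(as.character(groundTruth(y)$class),
               as.character(groundTruth(x)$class))
  unlink(dir, recursive = TRUE)
})
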