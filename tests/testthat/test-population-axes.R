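test_that("axis computation normalizes and rejects degenerate input", {
  ax <- computeAxis(c(3, 4), c(0, 0), kind = "sound")
  expect_equal(axisWeights(ax), c(0.6, 0.8))
  expect_equal(sqrt(sum(axisWeights(ax)^2)), 1, tolerance = 1e-12)
  expect_error(computeAxis(c(1, 2), c(1, 2)), "degenerate")
  expect_error(computeAxis(1:3, 1:2), "length")
})

test_that("engagement axis recovers the planted direction", {
  cfg <- synthConfig(
    nNeurons = c(Pyr = 30L, SOM = 4L, PV = 6L),
    nTrials = c(active = 110L, passive = 100L, spontaneous = 4L),
    noiseSd = 0.08, seed = 17L)
  x <- generateSession(cfg)
  con <- axisContrasts(x, "engagement")
  ax <- computeAxis(con$meanA, con$meanB, kind = "engagement")
  d <- S4Vectors::metadata(x)$engagement_direction
  expect_gt(abs(sum(axisWeights(ax) * d)), 0.95)
})

test_that("contrast vectors match the planted baseline shift", {
  cfg <- synthConfig(
    nNeurons = c(Pyr = 30L, SOM = 4L, PV = 6L),
    nTrials = c(active = 100L, passive = 100L, spontaneous = 4L),
    effectEngagement = 0.2, noiseSd = 0.03,
    coupleSound = 0, couplePhotostim = 0, seed = 19L)
  x <- generateSession(cfg)
  gt <- groundTruth(x)
  con <- axisContrasts(x, "engagement")
  diffVec <- con$meanA - con$meanB
  sound <- gt$class == "Sound"
  # sound-responsive neurons were shifted up by ~0.2 in active trials
  expect_equal(mean(diffVec[sound]), 0.2, tolerance = 0.03)
  expect_error(
    axisContrasts(generateSession(synthConfig(
      nNeurons = c(Pyr = 6L, SOM = 2L, PV = 2L),
      nTrials = c(active = 6L, passive = 5L, spontaneous = 3L),
      photostimTrialFraction = 0, seed = 1L)), "photostim"),
    "photostim")
})

test_that("cross-validated projections are leak-free bookkeeping", {
  x <- smallSession()
  cv <- crossvalProject(x, "engagement", kFolds = 4L, seed = 5L)

  # every active/passive trial projected exactly once
  nAP <- sum(trials(x)$context %in% c("active", "passive"))
  expect_equal(ncol(cv$projections), nAP)
  expect_equal(sort(unique(cv$trials$fold)), 1:4)
  expect_false(anyNA(cv$trials$pre))

  # all axes are unit norm
  for (ax in cv$axes)
    expect_equal(sqrt(sum(axisWeights(ax)^2)), 1, tolerance = 1e-9)

  # no-leak: perturbing only fold-1 test trials leaves the fold-1
  # axis unchanged (it is fit on the other folds)
  x2 <- x
  tr <- trials(x)
  f1 <- cv$trials$trial[cv$trials$fold == 1L]
  act2 <- activity(x2)
  for (t in f1) {
    cols <- tr$t_start[t]:tr$t_end[t]
    act2[, cols] <- act2[, cols] + 5
  }
  SummarizedExperiment::assay(x2, "activity") <- act2
  cv2 <- crossvalProject(x2, "engagement", kFolds = 4L, seed = 5L)
  expect_equal(axisWeights(cv2$axes[[1]]), axisWeights(cv$axes[[1]]),
               tolerance = 1e-12)

  # projection linearity: scaling the activity scales the projection
  x3 <- x
  SummarizedExperiment::assay(x3, "activity") <- 2 * activity(x)
  cv3 <- crossvalProject(x3, "engagement", kFolds = 4L, seed = 5L)
  expect_equal(cv3$projections, 2 * cv$projections, tolerance = 1e-9)

  # projecting the training difference vector returns its norm
  con <- axisContrasts(x, "engagement")
  d <- con$meanA - con$meanB
  ax <- computeAxis(con$meanA, con$meanB, kind = "engagement")
  expect_equal(sum(axisWeights(ax) * d), sqrt(sum(d^2)),
               tolerance = 1e-12)
})

test_that("axis stability across folds rises as noise falls", {
  stab <- vapply(c(0.3, 0.02), function(ns) {
    cfg <- synthConfig(
      nNeurons = c(Pyr = 20L, SOM = 3L, PV = 4L),
      nTrials = c(active = 40L, passive = 40L, spontaneous = 4L),
      noiseSd = ns, seed = 23L)
    cv <- crossvalProject(generateSession(cfg), "engagement", seed = 3L)
    w <- sapply(cv$axes, axisWeights)
    cs <- combn(ncol(w), 2, function(p) sum(w[, p[1]] * w[, p[2]]))
    mean(cs)
  }, numeric(1))
  expect_gt(stab[2], stab[1])
  expect_gt(stab[2], 0.98)
})

test_that("engagement-response coupling statistics", {
  xv <- seq(-1, 1, length.out = 30)
  cp <- engagementResponseCoupling(xv, 2 * xv)
  expect_equal(cp$r, 1, tolerance = 1e-12)
  expect_equal(cp$slope, 2, tolerance = 1e-12)

  # independent noise: r small, p roughly uniform over seeds
  set.seed(11)
  ps <- replicate(60, engagementResponseCoupling(rnorm(40),
                                                 rnorm(40))$p)
  expect_lt(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))

  expect_warning(z <- engagementResponseCoupling(rep(1, 10),
                                                 rnorm(10)),
                 "variance")
  expect_true(is.nan(z$r))
  expect_error(engagementResponseCoupling(1:2, 1:2), "3 paired")
})

test_that("planted coupling signs are recovered from projections", {
  x <- smallSession() # coupleSound > 0, couplePhotostim < 0
  eng <- crossvalProject(x, "engagement", seed = 2L)
  snd <- crossvalProject(x, "sound", seed = 2L)
  pht <- crossvalProject(x, "photostim", seed = 2L)
  cpS <- engagementResponseCoupling(eng$trials$pre, snd$trials$post)
  cpP <- engagementResponseCoupling(eng$trials$pre, pht$trials$post)
  expect_gt(cpS$r, 0)
  expect_lt(cpP$r, 0)
  expect_lt(cpS$p, 0.01)
})

test_that("performance-by-engagement binning and regression", {
  # all-correct trials: every retained bin at 1
  set.seed(3)
  ep <- runif(60, -0.9, 1.9)
  pf <- performanceByEngagement(ep, rep(TRUE, 60))
  expect_true(all(pf$bins$fraction_correct == 1))
  expect_true(all(pf$bins$n >= 5))

  # outcome independent of projection: slope near zero over seeds
  slopes <- vapply(1:25, function(s) {
    withr::with_seed(s, {
      e <- runif(200, -1, 2)
      ok <- runif(200) < 0.75
    })
    performanceByEngagement(e, ok)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)

  # planted logistic dependence: positive slope
  withr::with_seed(9, {
    e <- runif(400, -1, 2)
    ok <- runif(400) < plogis(1 + 1.5 * e)
  })
  expect_gt(performanceByEngagement(e, ok)$slope, 0)

  expect_error(performanceByEngagement(rep(0.2, 3), rep(TRUE, 3)),
               "underpopulated")
})

test_that("cell-type axis contributions", {
  w <- rep(1 / sqrt(9), 9)
  ax <- new("AxisModel", weights = w, axisKind = "engagement",
            foldId = NA_integer_, trainingTrials = integer())
  ct <- factor(rep(c("Pyr", "SOM", "PV"), each = 3))
  tab <- cellTypeAxisContribution(ax, ct)
  expect_equal(tab$mean_abs_weight, rep(1 / 3, 3))

  w2 <- c(0.6, 0.8, rep(0, 7))
  ax2 <- new("AxisModel", weights = w2, axisKind = "engagement",
             foldId = NA_integer_, trainingTrials = integer())
  ct2 <- factor(rep(c("Pyr", "SOM", "PV"), each = 3),
                levels = c("Pyr", "SOM", "PV"))
  tab2 <- cellTypeAxisContribution(ax2, ct2)
  expect_equal(tab2$mean_abs_weight[tab2$cell_type == "SOM"], 0)
  expect_equal(tab2$mean_abs_weight[tab2$cell_type == "PV"], 0)
  expect_error(cellTypeAxisContribution(ax2, ct2[1:5]), "label")
})
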