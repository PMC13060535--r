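test_that("alignment truncates segments to the shared minimum", {
  x <- manualExperiment(segA = 12L, segB = c(10L, 11L, 12L))
  al <- alignTruncate(x)
  # pre-s1 segment 12 (+1 for the event frame), s1->s2 5, s2->s3 5,
  # s3->turn truncated to 10, turn->reward 4, reward->end 6 (+1)
  expect_equal(dim(al$tensor), c(3L, 13L + 5L + 5L + 10L + 4L + 6L, 3L))
  expect_equal(unname(al$eventIndex["s1"]), 13)
  expect_equal(unname(diff(al$eventIndex[c("s3", "turn")])), 10)

  # identical trials: no truncation
  x2 <- manualExperiment(segB = c(10L, 10L, 10L))
  al2 <- alignTruncate(x2)
  expect_equal(dim(al2$tensor)[2], 13L + 5L + 5L + 10L + 4L + 6L)

  # a trial missing an event is dropped with a warning
  x3 <- manualExperiment()
  tr <- as.data.frame(trials(x3))
  tr$turn[2] <- NA
  x4 <- PPCExperiment(activity(x3), as.character(cellTypes(x3)), tr,
                      frameRate = 30)
  expect_warning(al4 <- alignTruncate(x4), "dropped")
  expect_equal(dim(al4$tensor)[1], 2L)
})

test_that("balanced subsets equalize the condition table", {
  tr <- data.frame(side = rep(c("l", "r"), each = 10),
                   choice = rep(c("l", "r", "l", "r"), each = 5))
  b <- balanceTrials(tr, "side", "choice", nRepeats = 3, seed = 1)
  expect_false(b$excluded)
  expect_equal(b$perCell, 5L)
  expect_true(all(lengths(b$repeats) == 20L))

  tr2 <- data.frame(side = c(rep("l", 10), rep("r", 10)),
                    choice = c(rep("l", 6), rep("r", 4),
                               rep("l", 5), rep("r", 5)))
  b2 <- balanceTrials(tr2, "side", "choice", nRepeats = 4, seed = 2)
  expect_equal(b2$perCell, 4L)
  expect_true(all(lengths(b2$repeats) == 16L))
  # repeats differ but are reproducible under the seed
  expect_false(identical(b2$repeats[[1]], b2$repeats[[2]]))
  b2b <- balanceTrials(tr2, "side", "choice", nRepeats = 4, seed = 2)
  expect_identical(b2$repeats, b2b$repeats)

  # any cell below the minimum excludes the dataset (no exception)
  tr3 <- data.frame(side = c(rep("l", 12), rep("r", 18)),
                    choice = c(rep("l", 3), rep("r", 9),
                               rep("l", 9), rep("r", 9)))
  b3 <- balanceTrials(tr3, "side", "choice")
  expect_true(b3$excluded)
})

test_that("population decoder: separability, chance, and Bayes rate", {
  set.seed(12)
  nTr <- 120
  lab <- rep(c("a", "b"), each = nTr / 2)

  # labels duplicated as features: perfect accuracy
  tens <- array(0, dim = c(nTr, 6, 4))
  tens[, , 1] <- (lab == "a") * 2 - 1
  tens[lab == "a", , ] <- tens[lab == "a", , ] + 0.01 * rnorm(sum(lab == "a") * 6 * 4)
  tens[, , 2:4] <- rnorm(nTr * 6 * 3)
  dp <- decodePopulation(tens, lab, spec = decodeSpec(binMs = 90),
                         frameRate = 30, seed = 1)
  expect_true(all(dp$accuracy > 95))

  # shuffled labels: accuracy consistent with chance
  expect_lt(max(abs(dp$shuffled - 50)), 3 * 100 * sqrt(0.25 / (0.3 * nTr)) + 10)

  # two-Gaussian populations at planted d': accuracy near the Bayes
  # rate Phi(d_total / 2) for equal-covariance classes
  d <- 1.5
  nTr2 <- 400
  lab2 <- rep(c("a", "b"), each = nTr2 / 2)
  tens2 <- array(rnorm(nTr2 * 3 * 2), dim = c(nTr2, 3, 2))
  shift <- ifelse(lab2 == "a", -d / 2, d / 2)
  tens2[, , 1] <- tens2[, , 1] + shift
  tens2[, , 2] <- tens2[, , 2] + shift
  bayes <- 100 * pnorm(sqrt(2) * d / 2)
  dp2 <- decodePopulation(tens2, lab2, spec = decodeSpec(binMs = 33),
                          frameRate = 30, seed = 3)
  se <- 100 * sqrt(bayes / 100 * (1 - bayes / 100) / (0.3 * nTr2))
  expect_lt(abs(mean(dp2$accuracy) - bayes), 3 * se + 2)
})

test_that("neuron subset modes", {
  ct <- factor(rep(c("Pyr", "SOM", "PV"), times = c(270, 14, 31)))
  s1 <- subsamplePopulations(ct, "by_type_all")
  expect_equal(lengths(s1), c(PV = 31L, Pyr = 270L, SOM = 14L))
  s2 <- subsamplePopulations(ct, "n_matched_random", seed = 4)
  expect_true(all(lengths(s2) == 14L))
  s2b <- subsamplePopulations(ct, "n_matched_random", seed = 4)
  expect_identical(s2, s2b)
  info <- c(0.9, 0.5, 0.2, 0.1, rep(0, 311))
  s3 <- subsamplePopulations(ct, "top_informative", info = info)
  expect_equal(s3$top[1:3], c(1L, 2L, 3L))
  expect_error(subsamplePopulations(factor(character()), "by_type_all"),
               "empty")
})

test_that("single-neuron information matches analytic references", {
  # deterministic channel: activity identical to the label -> 1 bit
  lab <- rep(c("a", "b"), each = 40)
  tf <- matrix(as.numeric(lab == "a"), ncol = 1)
  sn <- singleNeuronInformation(tf, lab, seed = 2)
  expect_equal(sn$peak, 1, tolerance = 1e-9)
  expect_true(sn$informative)

  # independent activity: near zero bits
  set.seed(5)
  tf0 <- matrix(rnorm(80), ncol = 1)
  sn0 <- singleNeuronInformation(tf0, lab, seed = 2)
  expect_lt(sn0$peak, 0.06)
  expect_false(sn0$informative)

  # Gaussian classes with known overlap: MI of the MAP decoder's
  # confusion matches the closed-form error-rate reference
  d <- 1.2
  nT <- 8000
  lab2 <- rep(c("a", "b"), each = nT / 2)
  set.seed(6)
  tf2 <- matrix(rnorm(nT) + ifelse(lab2 == "a", -d / 2, d / 2),
                ncol = 1)
  eps <- pnorm(-d / 2)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  miRef <- 1 - h(eps)
  sn2 <- singleNeuronInformation(tf2, lab2, seed = 3)
  expect_lt(abs(sn2$peak - miRef), 0.01)

  # peak restricted to the requested window
  tf3 <- cbind(tf2, matrix(as.numeric(lab2 == "a"), ncol = 1))
  sn3 <- singleNeuronInformation(tf3, lab2, window = 1L, seed = 3)
  expect_equal(sn3$peakFrame, 1L)
  expect_lt(sn3$peak, 0.9)
})
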