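test_that("generation is deterministic and files are byte-identical per seed", {
  cfg <- generatorConfig(nChains = 4, lengthRange = c(15, 25), seed = 8)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(a, b)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeDataset(a, d1, config = cfg)
  writeDataset(b, d2, config = cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  c_ <- generateDataset(generatorConfig(nChains = 4, lengthRange = c(15, 25),
                                        seed = 9))
  expect_false(identical(a, c_))
})

test_that("a written dataset read back reproduces the in-memory dataset exactly", {
  cfg <- generatorConfig(nChains = 5, lengthRange = c(20, 40), seed = 12)
  chains <- generateDataset(cfg)
  dir <- withr::local_tempdir()
  man <- writeDataset(chains, dir, config = cfg)
  back <- loadDataset(man)
  expect_equal(length(back), length(chains))
  for (i in seq_along(chains)) {
    expect_identical(chainSequence(back[[i]]), chainSequence(chains[[i]]))
    expect_identical(profilePercentages(back[[i]]),
                     profilePercentages(chains[[i]]))
    expect_identical(profileLogOdds(back[[i]]), profileLogOdds(chains[[i]]))
    expect_identical(chainAsa(back[[i]]), chainAsa(chains[[i]]))
    expect_identical(chainLabels(back[[i]]), chainLabels(chains[[i]]))
  }
})

test_that("interface labels are contiguous segments within length bounds", {
  cfg <- generatorConfig(nChains = 30, lengthRange = c(40, 70),
                         segmentLengthRange = c(5, 12), seed = 14)
  chains <- generateDataset(cfg)
  for (ch in as.list(chains)) {
    lab <- chainLabels(ch)
    r <- rle(lab)
    segs <- r$lengths[r$values == 1L]
    ## adjacent segments may abut and merge, so only the minimum is bounded
    if (length(segs))
      expect_true(all(segs >= 5))
  }
})

test_that("label marginal matches the configured segment rate", {
  ## long chains keep segment packing unconstrained, so the marginal is
  ## rate/100 * mean segment length
  cfg <- generatorConfig(nChains = 90, lengthRange = c(100, 150),
                         interfaceSegmentRate = 1.5,
                         segmentLengthRange = c(4, 8), seed = 15)
  chains <- generateDataset(cfg)
  lab <- unlist(lapply(as.list(chains), chainLabels))
  expect_gt(length(lab), 1e4)
  expected <- 1.5 / 100 * mean(4:8)
  expect_lt(abs(mean(lab) - expected), 0.015)
})

test_that("infeasible segment configurations raise errors", {
  cfg <- generatorConfig(nChains = 2, lengthRange = c(5, 5),
                         interfaceSegmentRate = 80,
                         segmentLengthRange = c(8, 9), seed = 2)
  expect_error(generateDataset(cfg), "infeasible")
  expect_error(generatorConfig(labelNoise = 0.6))
  expect_error(generatorConfig(lengthRange = c(10, 5)))
})

test_that("planted-model sampling approaches Viterbi labels at low temperature", {
  set.seed(5)
  planted <- hmsvmModel(W = rbind(-c(1.5, -1, 0.5), c(1.5, -1, 0.5)) / 2,
                        trans = matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  d <- generatePlantedModelDataset(planted, nChains = 10,
                                   lengthRange = c(10, 20),
                                   temperature = 1e-8, seed = 4)
  for (i in seq_along(d$X))
    expect_identical(d$labels[[i]], viterbiDecode(planted, d$X[[i]])$labels)
  expect_error(generatePlantedModelDataset(planted, 2, c(5, 10),
                                           temperature = 0), "temperature")
})

test_that("strong planted transitions lengthen label runs beyond iid expectation", {
  v <- c(1, -1, 0.5, 0, 0)
  planted <- hmsvmModel(W = rbind(-v / 2, v / 2),
                        trans = matrix(c(1.5, -1.5, -1.5, 1.5), 2, 2))
  d <- generatePlantedModelDataset(planted, nChains = 80,
                                   lengthRange = c(60, 60),
                                   temperature = 1, seed = 6)
  labs <- d$labels
  p <- mean(unlist(labs))
  nRuns <- sum(vapply(labs, function(y) length(rle(y)$lengths), numeric(1)))
  ## iid expectation of the run count at the same marginal
  expIid <- sum(vapply(labs, function(y)
    1 + (length(y) - 1) * 2 * p * (1 - p), numeric(1)))
  expect_lt(nRuns, 0.8 * expIid)
})

test_that("planted sampling is deterministic given the seed", {
  planted <- hmsvmModel(W = matrix(c(-1, 1), 2, 1))
  a <- generatePlantedModelDataset(planted, 5, c(10, 15), 1, seed = 3)
  b <- generatePlantedModelDataset(planted, 5, c(10, 15), 1, seed = 3)
  expect_identical(a, b)
})

test_that("held-out AUC grows with the planted composition signal", {
  aucAt <- function(shift) {
    cfg <- generatorConfig(nChains = 30, lengthRange = c(25, 45),
                           compositionShift = shift, asaShift = 0.1,
                           seed = 61)
    chains <- as.list(generateDataset(cfg))
    train <- ChainSet(chains[1:20])
    test <- ChainSet(chains[21:30])
    model <- trainHMSVM(train, trainingConfig(maxIter = 40),
                        featureConfig(windowHalf = 2))
    pred <- predictChains(model, test)
    rocAUC(pred$score, pred$gold, pred$surface)
  }
  aucs <- vapply(c(0, 0.8, 2.5), aucAt, numeric(1))
  expect_true(all(diff(aucs) > -0.01))
  expect_gt(aucs[3], aucs[1])
})
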