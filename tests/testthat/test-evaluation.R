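test_that("confusion counts match direct counting", {
  gold <- c(1L, 1L, 0L, 0L)
  expect_equal(confusionCounts(gold, c(1L, 0L, 1L, 0L)),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(confusionCounts(gold, gold)[c("FP", "FN")],
               c(FP = 0L, FN = 0L))
  allPos <- confusionCounts(gold, rep(1L, 4))
  expect_equal(allPos[["TN"]], 0L)
  expect_equal(allPos[["FP"]], 2L)
  ## masked and NA positions never count
  expect_equal(sum(confusionCounts(c(gold, NA), c(1L, 0L, 1L, 0L, 1L),
                                   c(TRUE, TRUE, FALSE, TRUE, TRUE))), 3)
  expect_error(confusionCounts(gold, gold, rep(FALSE, 4)), "empty")
})

test_that("metrics reproduce hand-derived values", {
  ## balanced symmetric point: MCC 0, Acc 0.5
  m <- metricsFromConfusion(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["acc"]], 0.5)

  ## perfection: everything 1
  p <- metricsFromConfusion(c(TP = 10, FP = 0, TN = 30, FN = 0))
  expect_equal(unname(p[c("sn", "sp", "precision", "acc", "f1", "mcc")]),
               rep(1, 6))

  ## TP=30 FP=10 FN=30 TN=30: Sn .5, Prec .75, F1 .6, Acc .6
  d <- metricsFromConfusion(c(TP = 30, FP = 10, TN = 30, FN = 30))
  expect_equal(d[["sn"]], 0.5)
  expect_equal(d[["precision"]], 0.75)
  expect_equal(d[["f1"]], 0.6)
  expect_equal(d[["acc"]], 0.6)
  expect_equal(d[["sp"]], 0.75)
  expect_equal(d[["mcc"]],
               (30 * 30 - 30 * 10) /
                 sqrt((30 + 30) * (30 + 10) * (30 + 10) * (30 + 30)))

  ## degenerate denominators report 0 with a note
  expect_message(z <- metricsFromConfusion(c(TP = 0, FP = 0, TN = 5, FN = 0)),
                 "degenerate")
  expect_equal(z[["sn"]], 0)
})

test_that("rank AUC matches the pairwise brute-force estimator", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.3), c(1L, 0L, 1L, 0L)), 0.75)
  expect_equal(rocAUC(c(3, 2, 1), c(1L, 1L, 0L)), 1.0)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(0L, 1L), 5)), 0.5)
  expect_error(rocAUC(1:4, rep(1L, 4)), "positive and one negative")

  set.seed(17)
  for (rep_ in 1:25) {
    n <- sample(5:200, 1)
    gold <- as.integer(runif(n) < 0.4)
    if (length(unique(gold)) < 2) next
    scores <- round(rnorm(n), 1)  # duplicates exercise the tie convention
    expect_equal(rocAUC(scores, gold), pairwiseAUC(scores, gold))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  gold <- as.integer(runif(300) < 0.3)
  scores <- rnorm(300) + gold
  expect_equal(rocAUC(scores, gold),
               as.numeric(pROC::auc(pROC::roc(gold, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("chain-level folds partition the chains", {
  ids <- sprintf("c%02d", 1:10)
  folds <- kfoldByChain(ids, k = 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 2))
  expect_equal(sort(names(folds)), sort(ids))
  expect_identical(folds, kfoldByChain(ids, k = 5, seed = 1))
  expect_false(identical(folds, kfoldByChain(ids, k = 5, seed = 2)))
  expect_error(kfoldByChain(ids[1:3], k = 5), "exceeds")
  expect_error(kfoldByChain(ids, k = 1), "at least 2")
})

test_that("cross-validation pools fold confusions additively and is deterministic", {
  chains <- generateDataset(generatorConfig(nChains = 15,
                                            lengthRange = c(25, 40),
                                            compositionShift = 1.5,
                                            asaShift = 0.3, seed = 31))
  cfg <- trainingConfig(maxIter = 30)
  fc <- featureConfig(windowHalf = 2)
  cv <- crossValidate(chains, cfg, fc, "basic+propensity", k = 3, seed = 1)
  perFoldSum <- Reduce(`+`, lapply(cv$perFold, confusionOf))
  expect_equal(perFoldSum[sort(names(perFoldSum))],
               confusionOf(cv$pooled)[sort(names(perFoldSum))])

  cv2 <- crossValidate(chains, cfg, fc, "basic+propensity", k = 3, seed = 1)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(metricsOf(cv$pooled), metricsOf(cv2$pooled))
})

test_that("test-fold labels never influence training (no leakage)", {
  chains <- generateDataset(generatorConfig(nChains = 12,
                                            lengthRange = c(20, 30),
                                            seed = 41))
  folds <- kfoldByChain(chains, k = 3, seed = 1)
  trainIdx <- which(folds != 1)
  testIdx <- which(folds == 1)
  train <- as.list(chains)[trainIdx]
  cfg <- trainingConfig(maxIter = 20)
  fc <- featureConfig(windowHalf = 2)
  modelA <- trainHMSVM(ChainSet(train), cfg, fc)

  ## corrupt every test-fold label; the trained model must be bit-identical
  corrupted <- as.list(chains)
  for (i in testIdx) {
    ch <- corrupted[[i]]
    ch@labels <- rev(ch@labels)
    corrupted[[i]] <- ch
  }
  modelB <- trainHMSVM(ChainSet(corrupted[trainIdx]), cfg, fc)
  expect_identical(modelA@W, modelB@W)
  expect_identical(modelA@trans, modelB@trans)
  expect_identical(modelA@propensity@scores, modelB@propensity@scores)
})

test_that("the ablation harness uses shared folds and exact report columns", {
  chains <- generateDataset(generatorConfig(nChains = 10,
                                            lengthRange = c(20, 30),
                                            compositionShift = 1.5,
                                            seed = 51))
  abl <- runAblation(chains, trainingConfig(maxIter = 20),
                     featureConfig(windowHalf = 1), k = 2, seed = 3)
  expect_identical(abl$basic$folds, abl$propensity$folds)
  expect_equal(abl$basic$pooled@featureSet, "basic")
  expect_equal(abl$propensity$pooled@featureSet, "basic+propensity")
  tab <- reportTable(abl)
  expect_true(all(c("Sp %", "Sn %", "F1 %", "Acc %", "MCC", "AUC %")
                  %in% colnames(tab)))
  expect_equal(nrow(tab), 2)
})
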