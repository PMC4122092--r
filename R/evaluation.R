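## Confusion-based metrics, rank AUC, chain-level k-fold cross-validation
## and the two-predictor (with/without propensity) ablation harness.

#' Confusion counts
#'
#' Counts TP/FP/TN/FN over masked positions; the positive class is
#' interface (label 1). By default the mask covers surface residues with a
#' known gold label — the evaluation universe of interface prediction.
#'
#' @param gold Integer 0/1 gold labels (NA allowed, never counted).
#' @param pred Integer 0/1 predicted labels.
#' @param mask Logical vector of evaluated positions; default all non-NA
#'   gold positions.
#' @return Named integer vector (TP, FP, TN, FN).
#' @export
confusionCounts <- function(gold, pred, mask = NULL) {
  stopifnot(length(gold) == length(pred))
  if (is.null(mask)) mask <- !is.na(gold)
  mask <- mask & !is.na(gold) & !is.na(pred)
  if (!any(mask)) stopData("empty evaluation mask")
  g <- gold[mask]
  p <- pred[mask]
  c(TP = sum(g == 1L & p == 1L),
    FP = sum(g == 0L & p == 1L),
    TN = sum(g == 0L & p == 0L),
    FN = sum(g == 1L & p == 0L))
}

#' Metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total,
#' Prec = TP/(TP+FP), F1 = 2*Prec*Sn/(Prec+Sn) and
#' MCC = (TP*TN - FN*FP)/sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' Specificity is the TN-based definition; precision is returned as a
#' separate entry because some interface-prediction reports print
#' precision under a "Sp" heading. Degenerate denominators yield 0 with a
#' diagnostic message. The MCC denominator is factored into a product of
#' square roots so it cannot overflow.
#'
#' @param counts Named vector with TP, FP, TN, FN.
#' @return Named numeric: sn, sp, precision, acc, f1, mcc.
#' @export
metricsFromConfusion <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]])
  fn <- as.numeric(counts[["FN"]])
  if (tp + fp + tn + fn <= 0) stopData("confusion counts sum to zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      message("degenerate denominator for ", what, "; reporting 0")
      0
    } else num / den
  }
  sn <- safe(tp, tp + fn, "sensitivity")
  sp <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  acc <- (tp + tn) / (tp + fp + tn + fn)
  f1 <- safe(2 * prec * sn, prec + sn, "F1")
  mccDen <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (mccDen == 0) {
    message("degenerate denominator for MCC; reporting 0")
    0
  } else max(-1, min(1, (tp * tn - fn * fp) / mccDen))
  c(sn = sn, sp = sp, precision = prec, acc = acc, f1 = f1, mcc = mcc)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC with half credit for ties, equal to the trapezoidal
#' area under the full ROC curve.
#'
#' @param scores Numeric ranking scores (higher = more interface-like).
#' @param gold Integer 0/1 gold labels.
#' @param mask Logical evaluated-position mask; default all non-NA gold.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, gold, mask = NULL) {
  stopifnot(length(scores) == length(gold))
  if (is.null(mask)) mask <- !is.na(gold)
  mask <- mask & !is.na(gold) & !is.na(scores)
  s <- scores[mask]
  g <- gold[mask]
  nPos <- sum(g == 1L)
  nNeg <- sum(g == 0L)
  if (nPos == 0L || nNeg == 0L)
    stopData("AUC needs at least one positive and one negative in the mask")
  r <- rank(s, ties.method = "average")
  (sum(r[g == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Chain-level k-fold assignment
#'
#' Chains (never residues) are partitioned into k near-equal folds by a
#' seeded shuffle, so no chain contributes residues to both a training and
#' a test split.
#'
#' @param chainIds Character vector of chain ids (or a [ChainSet-class]).
#' @param k Number of folds (>= 2). Default 5.
#' @param seed Shuffle seed. Default 1.
#' @return Named integer vector of fold ids in 1..k.
#' @export
kfoldByChain <- function(chainIds, k = 5L, seed = 1L) {
  if (is(chainIds, "ChainSet")) chainIds <- chainId(chainIds)
  n <- length(chainIds)
  if (k < 2L) stopData("k must be at least 2")
  if (k > n) stopData("k = ", k, " exceeds the number of chains (", n, ")")
  ord <- withSeed(deriveSeed(seed, "kfold"), sample.int(n))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  names(folds) <- chainIds
  folds
}

## Build an EvalReport from a predictions data.frame (columns gold, surface,
## predicted, score); the evaluation mask is surface & known-gold unless
## surfaceOnly is FALSE.
.reportFromPredictions <- function(pred, nChains, foldId, featureSet,
                                   surfaceOnly = TRUE) {
  mask <- !is.na(pred$gold) & (if (surfaceOnly) pred$surface else TRUE)
  counts <- confusionCounts(pred$gold, pred$predicted, mask)
  m <- metricsFromConfusion(counts)
  ## a small fold can be single-class; its AUC is then undefined
  auc <- tryCatch(rocAUC(pred$score, pred$gold, mask),
                  hmsvmPPI_data_error = function(e) {
                    message("AUC undefined for this evaluation: ",
                            conditionMessage(e))
                    NA_real_
                  })
  new("EvalReport", counts = counts,
      sn = m[["sn"]], sp = m[["sp"]], precision = m[["precision"]],
      acc = m[["acc"]], f1 = m[["f1"]], mcc = m[["mcc"]], auc = auc,
      nChains = as.integer(nChains), foldId = as.integer(foldId),
      featureSet = featureSet)
}

#' Chain-level cross-validation of one predictor
#'
#' For each fold: fits the propensity table and trains the model on the
#' training chains only (test labels can never reach either stage), then
#' predicts the held-out chains. Metrics are computed over surface residues
#' with known gold labels, per fold and pooled (micro-averaged over the
#' pooled confusion).
#'
#' @param chains A labelled [ChainSet-class].
#' @param trainConfig A [trainingConfig()].
#' @param featureCfg A [featureConfig()].
#' @param featureSet `"basic+propensity"` or `"basic"`.
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed (default 1).
#' @param folds Optional precomputed fold assignment (overrides k/seed).
#' @param surfaceOnly Evaluate over surface residues only (default TRUE).
#' @return List with `folds`, `perFold` (list of [EvalReport-class]),
#'   `pooled` ([EvalReport-class]) and `predictions` (data.frame with a
#'   fold column).
#' @export
crossValidate <- function(chains, trainConfig = trainingConfig(),
                          featureCfg = featureConfig(),
                          featureSet = c("basic+propensity", "basic"),
                          k = 5L, seed = 1L, folds = NULL,
                          surfaceOnly = TRUE) {
  featureSet <- match.arg(featureSet)
  chains <- as.list(chains)
  ids <- vapply(chains, chainId, character(1))
  if (is.null(folds)) folds <- kfoldByChain(ids, k = k, seed = seed)
  stopifnot(length(folds) == length(chains))
  perFold <- list()
  predAll <- NULL
  for (f in sort(unique(folds))) {
    trainChains <- ChainSet(chains[folds != f])
    testChains <- ChainSet(chains[folds == f])
    model <- trainHMSVM(trainChains, trainConfig, featureCfg, featureSet)
    pred <- predictChains(model, testChains)
    pred$fold <- f
    predAll <- rbind(predAll, pred)
    perFold[[as.character(f)]] <-
      .reportFromPredictions(pred, nChains = length(testChains),
                             foldId = f, featureSet = featureSet,
                             surfaceOnly = surfaceOnly)
  }
  pooled <- .reportFromPredictions(predAll, nChains = length(chains),
                                   foldId = NA_integer_,
                                   featureSet = featureSet,
                                   surfaceOnly = surfaceOnly)
  list(folds = folds, perFold = perFold, pooled = pooled,
       predictions = predAll)
}

#' Ablation: predictor with vs without the propensity feature
#'
#' Trains and evaluates two predictors under identical folds, seeds and
#' hyperparameters: the baseline on PSSM + relative ASA features
#' (D = 21*(2w+1)) and the full model with the order-profile propensity
#' appended (D = 22*(2w+1)). The propensity table is fitted per fold on
#' training chains only.
#'
#' @inheritParams crossValidate
#' @return List with `basic` and `propensity` cross-validation results
#'   (see [crossValidate()]) and the shared `folds`.
#' @export
runAblation <- function(chains, trainConfig = trainingConfig(),
                        featureCfg = featureConfig(),
                        k = 5L, seed = 1L, surfaceOnly = TRUE) {
  folds <- kfoldByChain(chains, k = k, seed = seed)
  basic <- crossValidate(chains, trainConfig, featureCfg, "basic",
                         folds = folds, surfaceOnly = surfaceOnly)
  prop <- crossValidate(chains, trainConfig, featureCfg, "basic+propensity",
                        folds = folds, surfaceOnly = surfaceOnly)
  list(basic = basic, propensity = prop, folds = folds)
}

#' Ablation report table
#'
#' One row per predictor with the conventional percentage-scaled columns
#' `Sp %`, `Sn %`, `F1 %`, `Acc %`, `MCC`, `AUC %` (from pooled confusion
#' counts), plus precision as `Prec %` for reports that use the
#' precision-based convention.
#'
#' @param ablation Result of [runAblation()].
#' @return A data.frame.
#' @export
reportTable <- function(ablation) {
  row <- function(name, rep) {
    data.frame(Method = name,
               `Sp %` = 100 * rep@sp,
               `Sn %` = 100 * rep@sn,
               `F1 %` = 100 * rep@f1,
               `Acc %` = 100 * rep@acc,
               MCC = rep@mcc,
               `AUC %` = 100 * rep@auc,
               `Prec %` = 100 * rep@precision,
               check.names = FALSE)
  }
  rbind(row("HM-SVM basic", ablation$basic$pooled),
        row("HM-SVM basic+propensity", ablation$propensity$pooled))
}
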