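## Generics and accessors. Slot access from user code goes through these.

#' @rdname ProteinChain-class
#' @param object,x A package object.
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname ProteinChain-class
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname ProteinChain-class
#' @export
setGeneric("chainLabels", function(x) standardGeneric("chainLabels"))

#' @rdname ProteinChain-class
#' @export
setGeneric("chainAsa", function(x) standardGeneric("chainAsa"))

#' @rdname ProteinChain-class
#' @export
setGeneric("profileLogOdds", function(x) standardGeneric("profileLogOdds"))

#' @rdname ProteinChain-class
#' @export
setGeneric("profilePercentages", function(x) standardGeneric("profilePercentages"))

#' @rdname ProteinChain-class
#' @export
setGeneric("datasetType", function(x) standardGeneric("datasetType"))

#' @rdname ProteinChain-class
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' @rdname PropensityTable-class
#' @export
setGeneric("propensityScores", function(x) standardGeneric("propensityScores"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname HMSVMModel-class
#' @export
setGeneric("emissionWeights", function(x) standardGeneric("emissionWeights"))

#' @rdname HMSVMModel-class
#' @export
setGeneric("transitionWeights", function(x) standardGeneric("transitionWeights"))

#' @rdname HMSVMModel-class
#' @export
setGeneric("labelBias", function(x) standardGeneric("labelBias"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionOf", function(x) standardGeneric("confusionOf"))

#' @rdname EvalReport-class
#' @export
setGeneric("metricsOf", function(x) standardGeneric("metricsOf"))

## ---- methods -------------------------------------------------------------

#' @rdname ProteinChain-class
setMethod("chainId", "ProteinChain", function(x) x@chainId)
#' @rdname ProteinChain-class
setMethod("chainSequence", "ProteinChain", function(x) x@sequence)
#' @rdname ProteinChain-class
setMethod("chainLabels", "ProteinChain", function(x) x@labels)
#' @rdname ProteinChain-class
setMethod("chainAsa", "ProteinChain", function(x) x@asa)
#' @rdname ProteinChain-class
setMethod("profileLogOdds", "ProteinChain", function(x) x@logOdds)
#' @rdname ProteinChain-class
setMethod("profilePercentages", "ProteinChain", function(x) x@percentages)
#' @rdname ProteinChain-class
setMethod("datasetType", "ProteinChain", function(x) x@datasetType)
#' @rdname ProteinChain-class
setMethod("chainLength", "ProteinChain", function(x) nchar(x@sequence))

#' @rdname ProteinChain-class
setMethod("chainId", "ChainSet", function(x)
  vapply(x, function(ch) ch@chainId, character(1)))

#' @rdname PropensityTable-class
#' @param x A [PropensityTable-class].
setMethod("propensityScores", "PropensityTable", function(x) x@scores)

#' @rdname FeatureMatrix-class
#' @param x A [FeatureMatrix-class].
setMethod("featureValues", "FeatureMatrix", function(x) x@X)

#' @rdname HMSVMModel-class
#' @param x An [HMSVMModel-class].
setMethod("emissionWeights", "HMSVMModel", function(x) x@W)
#' @rdname HMSVMModel-class
setMethod("transitionWeights", "HMSVMModel", function(x) x@trans)
#' @rdname HMSVMModel-class
setMethod("labelBias", "HMSVMModel", function(x) x@bias)

#' @rdname EvalReport-class
#' @param x An [EvalReport-class].
setMethod("confusionOf", "EvalReport", function(x) x@counts)
#' @rdname EvalReport-class
setMethod("metricsOf", "EvalReport", function(x)
  c(sn = x@sn, sp = x@sp, precision = x@precision, acc = x@acc,
    f1 = x@f1, mcc = x@mcc, auc = x@auc))

## ---- show ----------------------------------------------------------------

setMethod("show", "ProteinChain", function(object) {
  nInt <- sum(object@labels == 1L, na.rm = TRUE)
  cat(sprintf("ProteinChain '%s': %d residues, %d interface, %s\n",
              object@chainId, chainLength(object), nInt, object@datasetType))
})

setMethod("show", "ChainSet", function(object) {
  L <- vapply(object, chainLength, integer(1))
  cat(sprintf("ChainSet: %d chains, %d residues total\n",
              length(object), sum(L)))
})

setMethod("show", "PropensityTable", function(object) {
  cat(sprintf(paste0("PropensityTable: %d symbols (threshold %.2f, ",
                     "pseudocount %.2f)\n  interface/surface totals %d/%d, ",
                     "default score %.4f\n"),
              length(object@scores), object@threshold, object@pseudocount,
              as.integer(object@nInterface), as.integer(object@nSurface),
              object@defaultScore))
  if (length(object@scores)) {
    top <- sort(object@scores, decreasing = TRUE)
    k <- min(3L, length(top))
    cat("  top symbols:",
        paste(sprintf("%s (%.3f)", names(top)[seq_len(k)], top[seq_len(k)]),
              collapse = ", "), "\n")
  }
})

setMethod("show", "HMSVMModel", function(object) {
  cat(sprintf(paste0("HMSVMModel: feature set '%s', D = %d, half-window %d\n",
                     "  |W| = %.4f, |trans| = %.4f, bias = (%.4f, %.4f)\n"),
              object@featureSet, object@featureDim, object@windowHalf,
              sqrt(sum(object@W^2)), sqrt(sum(object@trans^2)),
              object@bias[1], object@bias[2]))
})

setMethod("show", "EvalReport", function(object) {
  fold <- if (is.na(object@foldId)) "pooled" else paste("fold", object@foldId)
  cat(sprintf("EvalReport (%s, %s): TP=%d FP=%d TN=%d FN=%d\n",
              object@featureSet, fold,
              object@counts[["TP"]], object@counts[["FP"]],
              object@counts[["TN"]], object@counts[["FN"]]))
  cat(sprintf("  Sn %.3f  Sp %.3f  Prec %.3f  Acc %.3f  F1 %.3f  MCC %.3f  AUC %.3f\n",
              object@sn, object@sp, object@precision, object@acc,
              object@f1, object@mcc, object@auc))
})
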