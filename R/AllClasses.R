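#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

## ---------------------------------------------------------------------------
## ProteinChain: one protein chain with its per-residue evidence and labels.
## ---------------------------------------------------------------------------

#' ProteinChain: per-residue evidence for one protein chain
#'
#' Holds the amino-acid sequence, the PSI-BLAST profile (both the 20 log-odds
#' and the 20 weighted-percentage columns, remapped to alphabetical
#' amino-acid order), per-residue absolute accessible surface area (ASA, in
#' square Angstroms) and interface labels. Labels are integer 1 (interface),
#' 0 (non-interface) or NA (unknown/excluded). `datasetType` records the
#' labelling convention: `"type_I"` counts minor-interface residues as
#' negatives, `"type_II"` as positives.
#'
#' @slot chainId Character scalar, e.g. PDB id plus chain letter.
#' @slot sequence Character scalar, uppercase one-letter amino acids.
#' @slot logOdds Integer-valued L x 20 matrix, alphabetical column order.
#' @slot percentages Integer-valued L x 20 matrix in [0, 100].
#' @slot asa Numeric length-L vector of absolute ASA, all >= 0.
#' @slot labels Integer length-L vector in {0, 1, NA}.
#' @slot datasetType `"type_I"` or `"type_II"`.
#'
#' @export
setClass("ProteinChain",
  representation(
    chainId = "character",
    sequence = "character",
    logOdds = "matrix",
    percentages = "matrix",
    asa = "numeric",
    labels = "integer",
    datasetType = "character"
  )
)

setValidity("ProteinChain", function(object) {
  L <- nchar(object@sequence)
  msgs <- character(0)
  if (length(object@chainId) != 1L || !nzchar(object@chainId))
    msgs <- c(msgs, "chainId must be a non-empty string")
  if (L < 1L)
    msgs <- c(msgs, "sequence must be non-empty")
  for (nm in c("logOdds", "percentages")) {
    m <- slot(object, nm)
    if (nrow(m) != L) msgs <- c(msgs, sprintf("%s must have one row per residue", nm))
    if (ncol(m) != 20L) msgs <- c(msgs, sprintf("%s must have 20 columns", nm))
  }
  if (any(object@percentages < 0 | object@percentages > 100))
    msgs <- c(msgs, "percentages must lie in [0, 100]")
  if (length(object@asa) != L)
    msgs <- c(msgs, "asa must have one value per residue")
  if (any(object@asa < 0))
    msgs <- c(msgs, "asa must be non-negative")
  if (length(object@labels) != L)
    msgs <- c(msgs, "labels must have one value per residue")
  if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
    msgs <- c(msgs, "labels must be 0, 1 or NA")
  if (!object@datasetType %in% c("type_I", "type_II"))
    msgs <- c(msgs, "datasetType must be 'type_I' or 'type_II'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinChain
#'
#' @param chainId Chain identifier.
#' @param sequence Amino-acid string (uppercased on input).
#' @param logOdds L x 20 PSSM log-odds matrix, alphabetical column order.
#' @param percentages L x 20 PSI-BLAST weighted-percentage matrix,
#'   alphabetical column order.
#' @param asa Numeric vector of absolute ASA per residue.
#' @param labels Integer vector of per-residue labels (1 interface,
#'   0 non-interface, NA unknown).
#' @param datasetType `"type_I"` (default) or `"type_II"`.
#' @return A [ProteinChain-class] object.
#' @export
ProteinChain <- function(chainId, sequence, logOdds, percentages, asa,
                         labels = rep(NA_integer_, nchar(sequence)),
                         datasetType = "type_I") {
  canon <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, aminoAcids())
    m
  }
  new("ProteinChain",
      chainId = as.character(chainId),
      sequence = toupper(as.character(sequence)),
      logOdds = canon(logOdds),
      percentages = canon(percentages),
      asa = as.numeric(asa),
      labels = as.integer(labels),
      datasetType = datasetType)
}

## ---------------------------------------------------------------------------
## ChainSet: an ordered collection of ProteinChain objects.
## ---------------------------------------------------------------------------

#' ChainSet: a dataset of protein chains
#'
#' A `SimpleList` of [ProteinChain-class] objects with unique chain ids;
#' the in-memory form of one dataset manifest.
#'
#' @export
setClass("ChainSet", contains = "SimpleList",
         prototype = prototype(elementType = "ProteinChain"))

setValidity("ChainSet", function(object) {
  if (length(object) == 0L) return(TRUE)
  ok <- vapply(object, is, logical(1), class2 = "ProteinChain")
  if (!all(ok)) return("all elements must be ProteinChain objects")
  ids <- vapply(object, function(ch) ch@chainId, character(1))
  if (anyDuplicated(ids)) return("chain ids must be unique")
  TRUE
})

#' Construct a ChainSet
#'
#' @param ... [ProteinChain-class] objects, or a single list of them.
#' @return A [ChainSet-class].
#' @export
ChainSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "ProteinChain"))
    args <- args[[1]]
  ids <- vapply(args, function(ch) ch@chainId, character(1))
  names(args) <- ids
  new("ChainSet", S4Vectors::SimpleList(args))
}

## ---------------------------------------------------------------------------
## PropensityTable: order-profile propensity scores.
## ---------------------------------------------------------------------------

#' PropensityTable: order-profile interface propensities
#'
#' Maps order-profile symbols (sets of high-frequency amino acids at a
#' profile position, written as an alphabetically sorted letter string) to a
#' smoothed log-odds propensity contrasting their occurrence among interface
#' residues against non-interface surface residues.
#'
#' @slot threshold Frequency cutoff in (0,1) used to form symbols.
#' @slot pseudocount Additive smoothing count (> 0).
#' @slot scores Named numeric vector, symbol -> propensity.
#' @slot defaultScore Propensity assigned to unseen symbols (the value the
#'   estimation formula gives a symbol with zero counts on both sides).
#' @slot nInterface,nSurface Occurrence totals used in estimation.
#'
#' @export
setClass("PropensityTable",
  representation(
    threshold = "numeric",
    pseudocount = "numeric",
    scores = "numeric",
    defaultScore = "numeric",
    nInterface = "numeric",
    nSurface = "numeric"
  )
)

setValidity("PropensityTable", function(object) {
  msgs <- character(0)
  if (object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must lie in (0, 1)")
  if (object@pseudocount <= 0)
    msgs <- c(msgs, "pseudocount must be positive")
  if (length(object@scores) && (is.null(names(object@scores)) ||
                                any(!nzchar(names(object@scores)))))
    msgs <- c(msgs, "scores must be named by symbol")
  if (any(!is.finite(object@scores)) || !is.finite(object@defaultScore))
    msgs <- c(msgs, "propensity scores must be finite")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## FeatureMatrix: encoded sliding-window features for one chain.
## ---------------------------------------------------------------------------

#' FeatureMatrix: per-residue window-encoded features
#'
#' Row i is the concatenation of per-residue feature vectors at offsets
#' -w..+w around residue i (zero-padded at chain ends). With the
#' `"basic"` feature set each position contributes 21 values (20
#' logistic-scaled PSSM log-odds, 1 relative ASA); `"basic+propensity"`
#' appends the order-profile propensity for 22, giving D = 22*(2w+1) = 286
#' at the default half-window w = 6.
#'
#' @slot chainId Chain identifier.
#' @slot X L x D numeric matrix.
#' @slot windowHalf Half-window w (>= 0).
#' @slot featureSet `"basic"`, `"basic+propensity"` or `"raw"`.
#'
#' @export
setClass("FeatureMatrix",
  representation(
    chainId = "character",
    X = "matrix",
    windowHalf = "integer",
    featureSet = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character(0)
  if (object@windowHalf < 0L)
    msgs <- c(msgs, "windowHalf must be >= 0")
  if (any(!is.finite(object@X)))
    msgs <- c(msgs, "feature values must be finite")
  perPos <- c(basic = 21L, `basic+propensity` = 22L)
  fs <- object@featureSet
  if (fs %in% names(perPos) &&
      ncol(object@X) != perPos[[fs]] * (2L * object@windowHalf + 1L))
    msgs <- c(msgs, "column count inconsistent with feature set and window")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## HMSVMModel: the trained linear-chain max-margin sequence labeler.
## ---------------------------------------------------------------------------

#' HMSVMModel: linear-chain max-margin sequence labeler
#'
#' Emission weights per label, per-label biases and first-order
#' label-transition weights for the two labels NEG (non-interface) and POS
#' (interface). Supports Viterbi decoding, loss-augmented decoding and
#' max-marginal scoring. A fitted [PropensityTable-class] and the feature
#' configuration are carried along so prediction is self-contained.
#'
#' @slot W 2 x D emission weight matrix (row 1 NEG, row 2 POS).
#' @slot trans 2 x 2 transition weight matrix, `trans[from, to]`.
#' @slot bias Length-2 per-label biases.
#' @slot featureDim D, must match the training FeatureMatrix.
#' @slot featureSet `"basic"`, `"basic+propensity"` or `"raw"`.
#' @slot windowHalf Half-window used for feature encoding.
#' @slot propensity A [PropensityTable-class] or NULL.
#' @slot config Snapshot of the training configuration plus the training log.
#'
#' @export
setClass("HMSVMModel",
  representation(
    W = "matrix",
    trans = "matrix",
    bias = "numeric",
    featureDim = "integer",
    featureSet = "character",
    windowHalf = "integer",
    propensity = "ANY",
    config = "list"
  )
)

setValidity("HMSVMModel", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@W), c(2L, object@featureDim)))
    msgs <- c(msgs, "W must be 2 x featureDim")
  if (!identical(dim(object@trans), c(2L, 2L)))
    msgs <- c(msgs, "trans must be 2 x 2")
  if (length(object@bias) != 2L)
    msgs <- c(msgs, "bias must have length 2")
  if (any(!is.finite(object@W)) || any(!is.finite(object@trans)) ||
      any(!is.finite(object@bias)))
    msgs <- c(msgs, "all weights must be finite")
  if (!is.null(object@propensity) && !is(object@propensity, "PropensityTable"))
    msgs <- c(msgs, "propensity must be NULL or a PropensityTable")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## EvalReport: confusion counts plus the derived metrics for one evaluation.
## ---------------------------------------------------------------------------

#' EvalReport: evaluation metrics for one fold or pooled
#'
#' Confusion counts over evaluated (by default surface) residues plus
#' sensitivity, specificity (TN/(TN+FP)), precision, accuracy, F1, Matthews
#' correlation and ranking AUC. Specificity follows the TN-based definition;
#' precision is exposed separately because some interface-prediction reports
#' print precision under the "Sp" heading.
#'
#' @slot counts Named integer vector (TP, FP, TN, FN).
#' @slot sn,sp,precision,acc,f1,mcc,auc Numeric metrics.
#' @slot nChains Number of chains evaluated.
#' @slot foldId Fold index, or NA for pooled reports.
#' @slot featureSet Feature set the evaluated model used.
#'
#' @export
setClass("EvalReport",
  representation(
    counts = "integer",
    sn = "numeric", sp = "numeric", precision = "numeric",
    acc = "numeric", f1 = "numeric", mcc = "numeric", auc = "numeric",
    nChains = "integer",
    foldId = "integer",
    featureSet = "character"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@counts)), sort(c("TP", "FP", "TN", "FN"))))
    msgs <- c(msgs, "counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative")
  for (nm in c("sn", "sp", "acc", "f1"))
    if (length(slot(object, nm)) == 1L && !is.na(slot(object, nm)) &&
        (slot(object, nm) < 0 || slot(object, nm) > 1))
      msgs <- c(msgs, sprintf("%s must lie in [0, 1]", nm))
  if (length(object@mcc) == 1L && !is.na(object@mcc) &&
      (object@mcc < -1 || object@mcc > 1))
    msgs <- c(msgs, "mcc must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})
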