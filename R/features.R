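## Feature engineering: frequency profiles, order-profile propensities,
## logistic PSSM scaling, relative solvent accessibility, sliding windows.

#' Feature configuration
#'
#' Collects every tunable of the feature stage. `threshold` is the profile
#' frequency cutoff that forms order-profile symbols; `propensityPseudocount`
#' smooths the propensity log-odds; `profilePseudocount` smooths percentage
#' rows into frequency distributions (so all-zero PSI-BLAST rows become
#' near-uniform); `windowHalf` is the number of neighbouring residues taken
#' on each side of the target; `surfaceThreshold` is the relative-ASA cutoff
#' defining surface residues; `asaClip` caps relative ASA (DSSP can exceed
#' nominal maxima).
#'
#' @param threshold Frequency cutoff in (0,1). Default 0.15.
#' @param propensityPseudocount Positive smoothing count. Default 1.
#' @param profilePseudocount Non-negative smoothing percentage. Default 1.
#' @param windowHalf Half-window w >= 0. Default 6.
#' @param surfaceThreshold Relative-ASA surface cutoff in [0,1]. Default 0.05.
#' @param maxAsa Named numeric table of nominal maximum ASA per residue type.
#' @param asaClip Upper clip for relative ASA. Default 1.2.
#' @return A list with class `featureConfig`.
#' @export
featureConfig <- function(threshold = 0.15,
                          propensityPseudocount = 1,
                          profilePseudocount = 1,
                          windowHalf = 6L,
                          surfaceThreshold = 0.05,
                          maxAsa = maxASATable(),
                          asaClip = 1.2) {
  stopifnot(threshold > 0, threshold < 1,
            propensityPseudocount > 0, profilePseudocount >= 0,
            windowHalf >= 0, surfaceThreshold >= 0, surfaceThreshold <= 1,
            all(maxAsa > 0))
  structure(list(threshold = threshold,
                 propensityPseudocount = propensityPseudocount,
                 profilePseudocount = profilePseudocount,
                 windowHalf = as.integer(windowHalf),
                 surfaceThreshold = surfaceThreshold,
                 maxAsa = maxAsa,
                 asaClip = asaClip),
            class = "featureConfig")
}

#' Percentages to frequency profile
#'
#' Converts PSI-BLAST weighted-percentage rows into per-position amino-acid
#' frequency distributions: row r becomes (pct + k) renormalised to sum 1,
#' which for rows summing to 100 equals (pct + k)/(100 + 20k). All-zero
#' rows (which PSI-BLAST emits for some residues) become uniform.
#'
#' @param percentages L x 20 matrix in [0, 100], alphabetical column order.
#' @param pseudocount Non-negative smoothing percentage k.
#' @return L x 20 matrix; each row sums to 1.
#' @export
percentagesToFrequencyProfile <- function(percentages, pseudocount = 1) {
  stopifnot(pseudocount >= 0, ncol(percentages) == 20L)
  m <- percentages + pseudocount
  rs <- rowSums(m)
  if (any(rs <= 0))
    stopNumeric("all-zero percentage row with zero pseudocount; ",
                "use a positive pseudocount")
  f <- m / rs
  colnames(f) <- aminoAcids()
  f
}

#' Order-profile symbol of one profile row
#'
#' The order profile at a position is the set of amino acids whose profile
#' frequency exceeds `threshold`, written as a string in alphabetical
#' order. If no frequency exceeds the threshold the symbol falls back to
#' the single amino acid of maximal frequency (ties resolved to the
#' alphabetically first).
#'
#' @param freqRow Numeric length-20 frequency vector (alphabetical order).
#' @param threshold Frequency cutoff in (0,1).
#' @return Single-character-string symbol, e.g. `"AK"`.
#' @export
toOrderProfile <- function(freqRow, threshold) {
  stopifnot(length(freqRow) == 20L, threshold > 0, threshold < 1)
  idx <- which(freqRow > threshold)
  if (length(idx) == 0L) idx <- which.max(freqRow)
  paste(aminoAcids()[idx], collapse = "")
}

## Vectorised over profile rows.
orderProfiles <- function(freq, threshold) {
  vapply(seq_len(nrow(freq)),
         function(i) toOrderProfile(freq[i, ], threshold),
         character(1))
}

#' Fit an order-profile propensity table
#'
#' For each order-profile symbol o observed among labelled surface residues
#' of the training chains, the propensity is the smoothed log-odds of its
#' occurrence among interface residues against non-interface surface
#' residues:
#' \deqn{score(o) = \log\frac{c_{int}(o)+\kappa}{N_{int}+\kappa S}
#'               - \log\frac{c_{surf}(o)+\kappa}{N_{surf}+\kappa S}}
#' where S is the number of distinct symbols seen and \eqn{\kappa} the
#' pseudocount. `defaultScore` is the same formula at zero counts and is
#' used for symbols never seen in training. Only labelled surface residues
#' contribute counts; the table is a learned statistic and must be fitted
#' on training chains only.
#'
#' @param chains A [ChainSet-class] or list of [ProteinChain-class].
#' @param config A [featureConfig()].
#' @return A [PropensityTable-class].
#' @export
fitPropensityTable <- function(chains, config = featureConfig()) {
  cInt <- new.env(parent = emptyenv())
  cSurf <- new.env(parent = emptyenv())
  nInt <- 0
  nSurf <- 0
  for (ch in as.list(chains)) {
    freq <- percentagesToFrequencyProfile(ch@percentages,
                                          config$profilePseudocount)
    sym <- orderProfiles(freq, config$threshold)
    rasa <- relativeAsa(ch@asa, ch@sequence, config$maxAsa, config$asaClip)
    surf <- surfaceMask(rasa, config$surfaceThreshold)
    lab <- ch@labels
    for (i in which(surf & !is.na(lab))) {
      envir <- if (lab[i] == 1L) cInt else cSurf
      envir[[sym[i]]] <- (if (is.null(envir[[sym[i]]])) 0 else envir[[sym[i]]]) + 1
      if (lab[i] == 1L) nInt <- nInt + 1 else nSurf <- nSurf + 1
    }
  }
  if (nInt == 0 || nSurf == 0)
    stopData("propensity estimation needs at least one interface and one ",
             "non-interface surface residue in the training chains")
  symbols <- sort(unique(c(ls(cInt), ls(cSurf))))
  S <- length(symbols)
  k <- config$propensityPseudocount
  getCount <- function(envir, s) if (is.null(envir[[s]])) 0 else envir[[s]]
  scoreOf <- function(ci, cs)
    log((ci + k) / (nInt + k * S)) - log((cs + k) / (nSurf + k * S))
  scores <- vapply(symbols,
                   function(s) scoreOf(getCount(cInt, s), getCount(cSurf, s)),
                   numeric(1))
  names(scores) <- symbols
  new("PropensityTable",
      threshold = config$threshold,
      pseudocount = k,
      scores = scores,
      defaultScore = scoreOf(0, 0),
      nInterface = nInt,
      nSurface = nSurf)
}

#' Propensity of order-profile symbols
#'
#' @param table A [PropensityTable-class].
#' @param symbols Character vector of symbols.
#' @return Numeric propensities; unseen symbols get the table's default.
#' @export
propensityOf <- function(table, symbols) {
  stopifnot(is(table, "PropensityTable"))
  out <- unname(table@scores[symbols])
  out[is.na(out)] <- table@defaultScore
  out
}

#' Logistic scaling of PSSM log-odds
#'
#' Squashes integer log-odds elementwise through 1/(1 + exp(-x)) into
#' (0, 1), the standard scaling for PSSM features fed to margin
#' classifiers.
#'
#' @param logOdds Numeric vector or matrix.
#' @return Same shape, values in (0, 1).
#' @export
scalePssm <- function(logOdds) 1 / (1 + exp(-logOdds))

#' Relative solvent accessibility
#'
#' Divides absolute ASA by the residue type's nominal maximum area and
#' clips to [0, `clip`] (DSSP values can exceed the nominal maxima).
#' Residue types absent from the table divide by the table mean.
#'
#' @param asa Numeric vector of absolute ASA (square Angstroms).
#' @param sequence Amino-acid string of equal length.
#' @param maxAsa Named numeric maximum-ASA table.
#' @param clip Upper clip; default 1.2.
#' @return Numeric vector of relative ASA in [0, clip].
#' @export
relativeAsa <- function(asa, sequence, maxAsa = maxASATable(), clip = 1.2) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(aa) == length(asa))
  denom <- unname(maxAsa[aa])
  denom[is.na(denom)] <- mean(maxAsa)
  pmin(pmax(asa / denom, 0), clip)
}

#' Surface mask
#'
#' A residue is a surface residue iff its relative ASA is at least
#' `threshold` (boundary inclusive).
#'
#' @param rasa Relative ASA vector.
#' @param threshold Cutoff in [0, 1]; default 0.05.
#' @return Logical vector.
#' @export
surfaceMask <- function(rasa, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  rasa >= threshold
}

#' Encode sliding windows
#'
#' Row i of the result concatenates the per-residue feature vectors at
#' offsets -w..+w around position i; offsets outside the chain contribute
#' an all-zero pad vector.
#'
#' @param feat L x d per-residue feature matrix.
#' @param w Half-window (>= 0).
#' @return L x (d*(2w+1)) matrix.
#' @export
encodeWindows <- function(feat, w) {
  if (w < 0) stop("window half-width must be >= 0")
  w <- as.integer(w)
  feat <- as.matrix(feat)
  L <- nrow(feat)
  d <- ncol(feat)
  padded <- rbind(matrix(0, w, d), feat, matrix(0, w, d))
  out <- matrix(0, L, d * (2L * w + 1L))
  for (o in 0:(2L * w))
    out[, (o * d + 1L):((o + 1L) * d)] <- padded[seq_len(L) + o, , drop = FALSE]
  out
}

## Per-residue 21- or 22-dimensional feature vectors for one chain:
## 20 logistic-scaled PSSM log-odds, relative ASA, and (for
## "basic+propensity") the order-profile propensity.
residueFeatureVectors <- function(chain, config, propensity = NULL,
                                  featureSet = c("basic+propensity", "basic")) {
  featureSet <- match.arg(featureSet)
  pssm <- scalePssm(chain@logOdds)
  rasa <- relativeAsa(chain@asa, chain@sequence, config$maxAsa, config$asaClip)
  feat <- cbind(pssm, rasa)
  if (featureSet == "basic+propensity") {
    if (is.null(propensity))
      stopData("feature set 'basic+propensity' needs a fitted PropensityTable")
    freq <- percentagesToFrequencyProfile(chain@percentages,
                                          config$profilePseudocount)
    sym <- orderProfiles(freq, config$threshold)
    ## squash the log-odds propensity through the same logistic as the PSSM
    ## columns so every feature lives on the (0,1) scale
    feat <- cbind(feat, scalePssm(propensityOf(propensity, sym)))
  }
  unname(feat)
}

#' Window-encoded features for one chain
#'
#' @param chain A [ProteinChain-class].
#' @param config A [featureConfig()].
#' @param propensity A fitted [PropensityTable-class] (required for the
#'   `"basic+propensity"` set).
#' @param featureSet `"basic+propensity"` (default) or `"basic"`.
#' @return A [FeatureMatrix-class] with D = 22*(2w+1) or 21*(2w+1) columns.
#' @export
featurizeChain <- function(chain, config = featureConfig(), propensity = NULL,
                           featureSet = c("basic+propensity", "basic")) {
  featureSet <- match.arg(featureSet)
  feat <- residueFeatureVectors(chain, config, propensity, featureSet)
  X <- encodeWindows(feat, config$windowHalf)
  new("FeatureMatrix", chainId = chain@chainId, X = X,
      windowHalf = config$windowHalf, featureSet = featureSet)
}

#' Window-encoded features for a dataset
#'
#' @param chains A [ChainSet-class].
#' @inheritParams featurizeChain
#' @return List of [FeatureMatrix-class], one per chain, named by chain id.
#' @export
featurizeChains <- function(chains, config = featureConfig(),
                            propensity = NULL,
                            featureSet = c("basic+propensity", "basic")) {
  featureSet <- match.arg(featureSet)
  out <- lapply(as.list(chains), featurizeChain, config = config,
                propensity = propensity, featureSet = featureSet)
  names(out) <- vapply(as.list(chains), chainId, character(1))
  out
}

#' Export a feature matrix as TSV
#'
#' One row per residue: chain id, 1-based index, the D feature columns and
#' the gold label (-1 for unknown).
#'
#' @param fm A [FeatureMatrix-class].
#' @param chain The matching [ProteinChain-class] (for labels).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
exportFeatures <- function(fm, chain, path) {
  stopifnot(is(fm, "FeatureMatrix"), is(chain, "ProteinChain"),
            identical(fm@chainId, chain@chainId))
  lab <- chain@labels
  lab[is.na(lab)] <- -1L
  df <- data.frame(chain_id = fm@chainId, index = seq_len(nrow(fm@X)),
                   fm@X, label = lab, check.names = FALSE)
  colnames(df) <- c("chain_id", "index",
                    paste0("f", seq_len(ncol(fm@X))), "label")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
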