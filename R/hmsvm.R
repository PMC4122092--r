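## The sequence-labeling learner: a linear-chain max-margin model with
## per-label emission weights, per-label biases and first-order transition
## weights, trained either by an averaged structured perceptron or by
## one-slack margin-rescaling cutting planes, decoded by Viterbi.
##
## Internal state indices are 1 = NEG (non-interface), 2 = POS (interface);
## public label vectors are integer 0/1. Exact ties in decoding are broken
## toward NEG at every step (which.max takes the first maximum), making
## predictions conservative and reproducible.

## ---- parameter packing ----------------------------------------------------
## theta = c(W[NEG, ], W[POS, ], bias[1:2], trans column-major (2x2)).

.thetaLen <- function(D) 2L * D + 6L

.unflatten <- function(theta, D) {
  list(W = rbind(theta[seq_len(D)], theta[D + seq_len(D)]),
       bias = theta[2L * D + (1:2)],
       trans = matrix(theta[2L * D + (3:6)], 2L, 2L))
}

## Joint feature map psi(X, y). `emissionMask` (when given) restricts the
## emission and bias components to masked positions; transition counts are
## always taken over the whole path, so transitions pass through excluded
## (e.g. buried) residues.
.psiVec <- function(X, states, emissionMask = NULL) {
  D <- ncol(X)
  L <- length(states)
  v <- numeric(.thetaLen(D))
  keep <- if (is.null(emissionMask)) rep(TRUE, L) else emissionMask
  for (k in 1:2) {
    rows <- which(states == k & keep)
    if (length(rows))
      v[(k - 1L) * D + seq_len(D)] <- colSums(X[rows, , drop = FALSE])
    v[2L * D + k] <- length(rows)
  }
  if (L > 1L)
    v[2L * D + (3:6)] <- tabulate(states[-L] + (states[-1L] - 1L) * 2L, 4L)
  v
}

## ---- decoding cores (operate on an L x 2 emission matrix) -----------------

.emissions <- function(W, bias, X) {
  E <- X %*% t(W)
  E[, 1L] <- E[, 1L] + bias[1L]
  E[, 2L] <- E[, 2L] + bias[2L]
  E
}

.pathScoreCore <- function(E, Tm, states) {
  L <- nrow(E)
  s <- sum(E[cbind(seq_len(L), states)])
  if (L > 1L) s <- s + sum(Tm[cbind(states[-L], states[-1L])])
  s
}

.decodeCore <- function(E, Tm) {
  L <- nrow(E)
  if (L == 0L) stopData("cannot decode an empty instance")
  delta <- E[1L, ]
  back <- matrix(1L, L, 2L)
  if (L > 1L) for (i in 2:L) {
    s1 <- delta + Tm[, 1L]
    s2 <- delta + Tm[, 2L]
    j1 <- which.max(s1)
    j2 <- which.max(s2)
    back[i, ] <- c(j1, j2)
    delta <- c(s1[j1] + E[i, 1L], s2[j2] + E[i, 2L])
  }
  yL <- which.max(delta)
  states <- integer(L)
  states[L] <- yL
  if (L > 1L) for (i in L:2) states[i - 1L] <- back[i, states[i]]
  list(states = states, score = delta[yL])
}

## Max-marginal score s_i = best path score with y_i = POS minus best with
## y_i = NEG, via forward/backward max recursions.
.maxMarginalCore <- function(E, Tm) {
  L <- nrow(E)
  if (L == 0L) stopData("cannot score an empty instance")
  a <- matrix(0, L, 2L)
  a[1L, ] <- E[1L, ]
  if (L > 1L) for (i in 2:L) {
    a[i, 1L] <- E[i, 1L] + max(a[i - 1L, ] + Tm[, 1L])
    a[i, 2L] <- E[i, 2L] + max(a[i - 1L, ] + Tm[, 2L])
  }
  b <- matrix(0, L, 2L)
  if (L > 1L) for (i in (L - 1L):1L) {
    b[i, 1L] <- max(Tm[1L, ] + E[i + 1L, ] + b[i + 1L, ])
    b[i, 2L] <- max(Tm[2L, ] + E[i + 1L, ] + b[i + 1L, ])
  }
  (a[, 2L] + b[, 2L]) - (a[, 1L] + b[, 1L])
}

## ---- public decoding API --------------------------------------------------

.featX <- function(model, X) {
  if (is(X, "FeatureMatrix")) X <- X@X
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopData("feature matrix contains non-finite values")
  if (ncol(X) != model@featureDim)
    stopData("feature dimension mismatch: model expects ", model@featureDim,
             " columns, got ", ncol(X))
  X
}

.toStates <- function(labels, L) {
  if (length(labels) != L)
    stopData("label vector length ", length(labels),
             " does not match instance length ", L)
  if (!all(labels %in% c(0L, 1L)))
    stopData("labels for scoring must be 0 or 1")
  as.integer(labels) + 1L
}

#' Construct a bare HMSVMModel from explicit weights
#'
#' Mainly for planted-model simulations and tests; ordinary users obtain
#' models from [trainHMSVM()].
#'
#' @param W 2 x D emission weight matrix (row 1 NEG, row 2 POS).
#' @param bias Length-2 per-label biases.
#' @param trans 2 x 2 transition weight matrix.
#' @param featureSet Feature-set tag; default `"raw"`.
#' @param windowHalf Window half-width used during encoding (metadata).
#' @param propensity Optional [PropensityTable-class].
#' @param config Optional configuration list.
#' @return An [HMSVMModel-class].
#' @export
hmsvmModel <- function(W, bias = c(0, 0), trans = matrix(0, 2, 2),
                       featureSet = "raw", windowHalf = 0L,
                       propensity = NULL, config = list()) {
  W <- as.matrix(W)
  new("HMSVMModel", W = W, trans = as.matrix(trans), bias = as.numeric(bias),
      featureDim = ncol(W), featureSet = featureSet,
      windowHalf = as.integer(windowHalf), propensity = propensity,
      config = config)
}

#' Score a labeling under the model
#'
#' The linear-chain potential: sum over positions of the emission score of
#' the assigned label plus sum over adjacent pairs of the transition weight.
#'
#' @param model An [HMSVMModel-class].
#' @param X L x D feature matrix (or [FeatureMatrix-class]).
#' @param labels Integer 0/1 labeling of length L.
#' @return The path potential (a scalar).
#' @export
pathScore <- function(model, X, labels) {
  X <- .featX(model, X)
  states <- .toStates(labels, nrow(X))
  E <- .emissions(model@W, model@bias, X)
  .pathScoreCore(E, model@trans, states)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring labeling; exact ties are resolved toward
#' the negative label at every backtracking step.
#'
#' @inheritParams pathScore
#' @return List with `labels` (integer 0/1), `score` (the path potential,
#'   recomputable via [pathScore()]) and `margins` (per-position
#'   max-marginal scores, see [maxMarginalScores()]).
#' @export
viterbiDecode <- function(model, X) {
  X <- .featX(model, X)
  E <- .emissions(model@W, model@bias, X)
  dec <- .decodeCore(E, model@trans)
  list(labels = dec$states - 1L, score = dec$score,
       margins = .maxMarginalCore(E, model@trans))
}

#' Loss-augmented Viterbi decoding
#'
#' Finds the labeling maximising path score plus the (masked) Hamming loss
#' against `goldLabels` — the most violated constraint of margin-rescaling
#' training. With an all-false mask this reduces to [viterbiDecode()].
#'
#' @inheritParams pathScore
#' @param goldLabels Integer 0/1 gold labeling (NA allowed; NA positions
#'   never contribute loss).
#' @param trainableMask Logical vector: positions contributing Hamming loss.
#'   Default: every non-NA gold position.
#' @return List with `labels` (integer 0/1) and `score` (potential plus
#'   loss of the returned labeling).
#' @export
lossAugmentedDecode <- function(model, X, goldLabels, trainableMask = NULL) {
  X <- .featX(model, X)
  L <- nrow(X)
  if (length(goldLabels) != L)
    stopData("gold label length does not match instance length")
  if (is.null(trainableMask)) trainableMask <- !is.na(goldLabels)
  trainableMask <- trainableMask & !is.na(goldLabels)
  E <- .emissions(model@W, model@bias, X)
  gold <- as.integer(goldLabels) + 1L
  for (k in 1:2) {
    mism <- which(trainableMask & gold != k)
    E[mism, k] <- E[mism, k] + 1
  }
  dec <- .decodeCore(E, model@trans)
  list(labels = dec$states - 1L, score = dec$score)
}

#' Per-position max-marginal scores
#'
#' s_i = (best path score with position i labelled interface) minus (best
#' with position i non-interface). Positive s_i means the Viterbi label at
#' i is interface (up to exact ties). These scores rank residues for ROC
#' analysis.
#'
#' @inheritParams pathScore
#' @return Numeric vector of length L.
#' @export
maxMarginalScores <- function(model, X) {
  X <- .featX(model, X)
  E <- .emissions(model@W, model@bias, X)
  .maxMarginalCore(E, model@trans)
}

## ---- training configuration ----------------------------------------------

#' Training configuration
#'
#' `c` trades margin violations against regularisation in the objective
#' 1/2 ||(W, b, T)||^2 + c * xi over the one-slack constraint set with
#' chain-averaged margins and losses; `epsilon` is the cutting-plane
#' termination tolerance on constraint violation (in chain-averaged Hamming
#' units). Defaults c = 0.1 and epsilon = 1 follow the SVM^hmm settings
#' this model class is conventionally run with.
#'
#' @param c Regularisation trade-off, > 0. Default 0.1.
#' @param epsilon Cutting-plane tolerance, > 0. Default 1.
#' @param algorithm `"one_slack_ssvm"` (default) or `"perceptron"`.
#' @param maxIter Iteration cap: cutting-plane rounds, or perceptron epochs.
#'   Default 200 for the SSVM, 50 for the perceptron.
#' @param seed Seed for the perceptron's chain shuffling (the SSVM is
#'   deterministic).
#' @param includeBuried If TRUE, buried residues also contribute Hamming
#'   loss during training; by default they are excluded via the trainable
#'   mask but remain in the chain so transitions pass through them.
#' @return A list with class `trainingConfig`.
#' @export
trainingConfig <- function(c = 0.1, epsilon = 1,
                           algorithm = c("one_slack_ssvm", "perceptron"),
                           maxIter = NULL, seed = 1L,
                           includeBuried = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(maxIter))
    maxIter <- if (algorithm == "perceptron") 50L else 200L
  stopifnot(c > 0, epsilon > 0, maxIter >= 1)
  structure(list(c = c, epsilon = epsilon, algorithm = algorithm,
                 maxIter = as.integer(maxIter), seed = as.integer(seed),
                 includeBuried = includeBuried),
            class = "trainingConfig")
}

## ---- low-level trainers ---------------------------------------------------

## Normalise raw inputs: feature matrices, gold states (NA gold -> NEG with
## mask forced FALSE), trainable masks.
.prepTraining <- function(XList, yList, maskList) {
  n <- length(XList)
  if (n == 0L) stopData("training set is empty")
  XList <- lapply(XList, function(x) if (is(x, "FeatureMatrix")) x@X else as.matrix(x))
  D <- ncol(XList[[1L]])
  if (!all(vapply(XList, ncol, integer(1)) == D))
    stopData("inconsistent feature dimensions across training chains")
  if (is.null(maskList)) maskList <- lapply(yList, function(y) !is.na(y))
  gold <- vector("list", n)
  for (i in seq_len(n)) {
    y <- yList[[i]]
    if (length(y) != nrow(XList[[i]]))
      stopData("gold labels and features disagree in length for chain ", i)
    m <- maskList[[i]] & !is.na(y)
    y[is.na(y)] <- 0L
    gold[[i]] <- as.integer(y) + 1L
    maskList[[i]] <- m
  }
  list(X = XList, gold = gold, mask = maskList, n = n, D = D)
}

.trainHamming <- function(theta, prep) {
  par <- .unflatten(theta, prep$D)
  errs <- 0L
  for (i in seq_len(prep$n)) {
    E <- .emissions(par$W, par$bias, prep$X[[i]])
    dec <- .decodeCore(E, par$trans)
    errs <- errs + sum(prep$mask[[i]] & dec$states != prep$gold[[i]])
  }
  errs
}

## Averaged structured perceptron. On each visited chain, Viterbi-decode and
## update by the feature difference of the gold vs predicted path, with
## emission/bias components restricted to trainable positions. If an epoch
## completes without mistakes the current (separating) weights are returned;
## if maxIter is exhausted the averaged weights are returned with a warning.
.perceptronFit <- function(prep, config) {
  P <- .thetaLen(prep$D)
  theta <- numeric(P)
  thetaSum <- numeric(P)
  t <- 0
  converged <- FALSE
  log <- NULL
  for (epoch in seq_len(config$maxIter)) {
    ord <- withSeed(deriveSeed(config$seed, paste0("perceptron-epoch-", epoch)),
                    sample.int(prep$n))
    errs <- 0L
    for (i in ord) {
      par <- .unflatten(theta, prep$D)
      E <- .emissions(par$W, par$bias, prep$X[[i]])
      dec <- .decodeCore(E, par$trans)
      wrong <- prep$mask[[i]] & dec$states != prep$gold[[i]]
      if (any(wrong)) {
        theta <- theta +
          .psiVec(prep$X[[i]], prep$gold[[i]], prep$mask[[i]]) -
          .psiVec(prep$X[[i]], dec$states, prep$mask[[i]])
        errs <- errs + sum(wrong)
      }
      thetaSum <- thetaSum + theta
      t <- t + 1
    }
    log <- rbind(log, data.frame(iter = epoch, errors = errs))
    if (errs == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("perceptron did not converge in ", config$maxIter,
            " epochs; returning averaged weights")
    theta <- thetaSum / t
  }
  list(theta = theta, converged = converged, trainingLog = log)
}

## Quadratic subproblem of the one-slack dual: maximise l'a - a'Ga/2 over
## {a >= 0, sum(a) <= C}. Projected coordinate ascent plus SMO-style pairwise
## transfers (needed for progress when the budget constraint is active),
## iterated to KKT residual < 1e-8.
.solveDual <- function(G, l, C, alpha) {
  K <- length(l)
  grad <- l - as.vector(G %*% alpha)
  kkt <- function() {
    lambda <- if (C - sum(alpha) > 1e-10) 0 else {
      act <- alpha > 1e-12
      if (any(act)) max(0, max(grad[act])) else 0
    }
    resid <- ifelse(alpha > 1e-12, abs(grad - lambda),
                    pmax(0, grad - lambda))
    max(resid)
  }
  for (sweep in seq_len(2000L)) {
    for (k in seq_len(K)) {
      if (G[k, k] <= 0) next
      budget <- C - sum(alpha) + alpha[k]
      anew <- min(max(alpha[k] + grad[k] / G[k, k], 0), budget)
      d <- anew - alpha[k]
      if (abs(d) > 0) {
        alpha[k] <- anew
        grad <- grad - d * G[, k]
      }
    }
    if (K > 1L && C - sum(alpha) <= 1e-10) {
      for (k in seq_len(K - 1L)) for (j in (k + 1L):K) {
        den <- G[k, k] - 2 * G[j, k] + G[j, j]
        if (den <= 0) next
        t <- (grad[k] - grad[j]) / den
        t <- min(max(t, -alpha[k]), alpha[j])
        if (abs(t) > 0) {
          alpha[k] <- alpha[k] + t
          alpha[j] <- alpha[j] - t
          grad <- grad - t * (G[, k] - G[, j])
        }
      }
    }
    if (kkt() < 1e-8) break
  }
  alpha
}

## One-slack margin-rescaling cutting-plane training (the SVM^hmm-style
## optimiser): repeatedly find the most violated joint constraint via
## loss-augmented decoding over all chains, add it to the working set, and
## re-solve the dual QP, until the most violated constraint is violated by
## at most epsilon. Margins and losses are averaged over chains; the primal
## objective is 1/2 ||theta||^2 + c * xi.
.ssvmFit <- function(prep, config) {
  n <- prep$n
  D <- prep$D
  P <- .thetaLen(D)
  psiGold <- lapply(seq_len(n), function(i) .psiVec(prep$X[[i]], prep$gold[[i]]))
  theta <- numeric(P)
  gmat <- matrix(0, P, 0)
  lvec <- numeric(0)
  G <- matrix(0, 0, 0)
  alpha <- numeric(0)
  prevDual <- -Inf
  log <- NULL
  converged <- FALSE
  for (it in seq_len(config$maxIter)) {
    par <- .unflatten(theta, D)
    gbar <- numeric(P)
    lbar <- 0
    for (i in seq_len(n)) {
      E <- .emissions(par$W, par$bias, prep$X[[i]])
      gold <- prep$gold[[i]]
      for (k in 1:2) {
        mism <- which(prep$mask[[i]] & gold != k)
        E[mism, k] <- E[mism, k] + 1
      }
      dec <- .decodeCore(E, par$trans)
      gbar <- gbar + psiGold[[i]] - .psiVec(prep$X[[i]], dec$states)
      lbar <- lbar + sum(prep$mask[[i]] & dec$states != gold)
    }
    gbar <- gbar / n
    lbar <- lbar / n
    xi <- if (length(lvec))
      max(0, max(lvec - as.vector(crossprod(gmat, theta)))) else 0
    viol <- lbar - sum(theta * gbar) - xi
    dual <- sum(alpha * lvec) - 0.5 * sum(theta^2)
    log <- rbind(log, data.frame(iter = it,
                                 primal = 0.5 * sum(theta^2) + config$c * xi,
                                 dual = dual, violation = viol,
                                 wsSize = length(lvec)))
    if (viol <= config$epsilon) {
      converged <- TRUE
      break
    }
    ## grow the working set and re-solve the dual
    newCross <- if (ncol(gmat)) as.vector(crossprod(gmat, gbar)) else numeric(0)
    gmat <- cbind(gmat, gbar)
    lvec <- c(lvec, lbar)
    G <- rbind(cbind(G, newCross), c(newCross, sum(gbar^2)))
    alpha <- .solveDual(G, lvec, config$c, c(alpha, 0))
    theta <- as.vector(gmat %*% alpha)
    dualNew <- sum(alpha * lvec) - 0.5 * sum(theta^2)
    if (dualNew < prevDual - 1e-8)
      stopNumeric("internal assertion failure: cutting-plane dual objective ",
                  "decreased (", prevDual, " -> ", dualNew, ")")
    prevDual <- dualNew
  }
  if (!converged)
    warning("SSVM reached maxIter = ", config$maxIter,
            " with violation above epsilon")
  list(theta = theta, converged = converged, trainingLog = log)
}

#' Fit HM-SVM weights from raw feature matrices
#'
#' Low-level trainer operating on lists of per-chain feature matrices, gold
#' labels and trainable masks. Most users should call [trainHMSVM()], which
#' also fits the propensity table and encodes windows.
#'
#' @param XList List of L_i x D feature matrices.
#' @param yList List of integer 0/1 label vectors (NA allowed: excluded
#'   from loss).
#' @param maskList Optional list of logical trainable masks.
#' @param config A [trainingConfig()].
#' @return List with `W`, `bias`, `trans`, `converged`, `trainingLog` and
#'   `trainHamming` (Hamming error of the returned weights on the
#'   training set).
#' @export
svmhmmFit <- function(XList, yList, maskList = NULL,
                      config = trainingConfig()) {
  prep <- .prepTraining(XList, yList, maskList)
  fit <- if (config$algorithm == "perceptron") .perceptronFit(prep, config)
         else .ssvmFit(prep, config)
  par <- .unflatten(fit$theta, prep$D)
  list(W = par$W, bias = par$bias, trans = par$trans,
       converged = fit$converged, trainingLog = fit$trainingLog,
       trainHamming = .trainHamming(fit$theta, prep))
}

## ---- high-level training and prediction -----------------------------------

## Gold labels and trainable mask for one chain under a feature config.
.chainTargets <- function(chain, featureCfg, includeBuried = FALSE) {
  rasa <- relativeAsa(chain@asa, chain@sequence, featureCfg$maxAsa,
                      featureCfg$asaClip)
  surf <- surfaceMask(rasa, featureCfg$surfaceThreshold)
  lab <- chain@labels
  mask <- !is.na(lab) & (includeBuried | surf)
  list(labels = lab, mask = mask, surface = surf)
}

#' Train an interface predictor on a set of chains
#'
#' Fits the order-profile propensity table on the given (training) chains,
#' encodes sliding-window features, and trains the linear-chain max-margin
#' model. Buried residues get the default propensity and stay in the chain
#' (transitions pass through them) but are excluded from the training loss
#' unless `includeBuried` is set in the training config.
#'
#' @param chains A [ChainSet-class] with labels.
#' @param trainConfig A [trainingConfig()].
#' @param featureCfg A [featureConfig()].
#' @param featureSet `"basic+propensity"` (default) or `"basic"`.
#' @return A fitted [HMSVMModel-class] carrying the propensity table,
#'   feature configuration and training log.
#' @export
trainHMSVM <- function(chains, trainConfig = trainingConfig(),
                       featureCfg = featureConfig(),
                       featureSet = c("basic+propensity", "basic")) {
  featureSet <- match.arg(featureSet)
  propensity <- if (featureSet == "basic+propensity")
    fitPropensityTable(chains, featureCfg) else NULL
  fmList <- featurizeChains(chains, featureCfg, propensity, featureSet)
  targets <- lapply(as.list(chains), .chainTargets, featureCfg = featureCfg,
                    includeBuried = isTRUE(trainConfig$includeBuried))
  fit <- svmhmmFit(lapply(fmList, featureValues),
                   lapply(targets, `[[`, "labels"),
                   lapply(targets, `[[`, "mask"),
                   config = trainConfig)
  cfg <- list(training = unclass(trainConfig),
              feature = .featureCfgMeta(featureCfg),
              trainingLog = fit$trainingLog,
              converged = fit$converged,
              trainHamming = fit$trainHamming)
  cfg$configHash <- configHash(cfg[c("training", "feature")])
  new("HMSVMModel", W = fit$W, trans = fit$trans, bias = fit$bias,
      featureDim = ncol(fit$W), featureSet = featureSet,
      windowHalf = featureCfg$windowHalf, propensity = propensity,
      config = cfg)
}

.featureCfgMeta <- function(cfg) {
  list(threshold = cfg$threshold,
       propensityPseudocount = cfg$propensityPseudocount,
       profilePseudocount = cfg$profilePseudocount,
       windowHalf = cfg$windowHalf,
       surfaceThreshold = cfg$surfaceThreshold,
       maxAsa = as.list(cfg$maxAsa),
       asaClip = cfg$asaClip)
}

.featureCfgFromMeta <- function(meta) {
  featureConfig(threshold = meta$threshold,
                propensityPseudocount = meta$propensityPseudocount,
                profilePseudocount = meta$profilePseudocount,
                windowHalf = meta$windowHalf,
                surfaceThreshold = meta$surfaceThreshold,
                maxAsa = unlist(meta$maxAsa),
                asaClip = meta$asaClip)
}

#' Predict interface residues for a set of chains
#'
#' Encodes each chain with the model's own feature configuration and
#' propensity table, Viterbi-decodes, and attaches per-residue max-marginal
#' scores.
#'
#' @param model A fitted [HMSVMModel-class].
#' @param chains A [ChainSet-class].
#' @return A data.frame with columns chain_id, index, gold (NA when
#'   unknown), surface (logical), predicted (0/1) and score.
#' @export
predictChains <- function(model, chains) {
  featureCfg <- .featureCfgFromMeta(model@config$feature)
  rows <- lapply(as.list(chains), function(ch) {
    fm <- featurizeChain(ch, featureCfg, model@propensity, model@featureSet)
    dec <- viterbiDecode(model, fm)
    rasa <- relativeAsa(ch@asa, ch@sequence, featureCfg$maxAsa,
                        featureCfg$asaClip)
    data.frame(chain_id = ch@chainId,
               index = seq_len(chainLength(ch)),
               gold = ch@labels,
               surface = surfaceMask(rasa, featureCfg$surfaceThreshold),
               predicted = dec$labels,
               score = dec$margins,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
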