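## Independent oracles: exhaustive enumeration over all 2^L labelings and a
## pairwise AUC estimator. These deliberately share no code with the
## dynamic-programming implementations they check.

enumLabelings <- function(L) {
  as.matrix(expand.grid(rep(list(0:1), L)))
}

## Direct arithmetic evaluation of the linear-chain potential.
oracleScore <- function(W, bias, trans, X, y01) {
  s <- 0
  for (i in seq_along(y01)) {
    k <- y01[i] + 1L
    s <- s + sum(W[k, ] * X[i, ]) + bias[k]
    if (i > 1L) s <- s + trans[y01[i - 1L] + 1L, k]
  }
  s
}

oracleAllScores <- function(model, X, gold = NULL, mask = NULL,
                            lossAug = FALSE) {
  labs <- enumLabelings(nrow(X))
  scores <- apply(labs, 1L, function(y) {
    s <- oracleScore(model@W, model@bias, model@trans, X, y)
    if (lossAug) s <- s + sum(mask & y != gold)
    s
  })
  list(labelings = labs, scores = scores)
}

oracleBest <- function(model, X, gold = NULL, mask = NULL, lossAug = FALSE) {
  o <- oracleAllScores(model, X, gold, mask, lossAug)
  best <- which.max(o$scores)
  list(labels = unname(o$labelings[best, ]), score = o$scores[best])
}

oracleMaxMarginals <- function(model, X) {
  o <- oracleAllScores(model, X)
  vapply(seq_len(nrow(X)), function(i) {
    max(o$scores[o$labelings[, i] == 1]) -
      max(o$scores[o$labelings[, i] == 0])
  }, numeric(1))
}

## AUC by brute force over all positive x negative pairs, half credit ties.
pairwiseAUC <- function(scores, gold) {
  pos <- scores[gold == 1]
  neg <- scores[gold == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

randomModel <- function(D) {
  hmsvmModel(W = matrix(rnorm(2 * D), 2, D), bias = rnorm(2),
             trans = matrix(rnorm(4), 2, 2))
}
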