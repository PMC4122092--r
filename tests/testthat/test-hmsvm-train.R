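## A separable low-level training set: the first feature carries the label
## with a hard margin, remaining features are noise.
separableSet <- function(nChains, L, D = 4, seed = 1) {
  set.seed(seed)
  XList <- list()
  yList <- list()
  for (i in seq_len(nChains)) {
    y <- as.integer(runif(L) < 0.3)
    X <- matrix(rnorm(L * D, sd = 0.2), L, D)
    X[, 1] <- (2 * y - 1) * (1 + runif(L, 0, 0.5))
    XList[[i]] <- X
    yList[[i]] <- y
  }
  list(X = XList, y = yList)
}

test_that("the structured perceptron drives a separable set to zero Hamming error", {
  d <- separableSet(10, 20, seed = 2)
  fit <- svmhmmFit(d$X, d$y,
                   config = trainingConfig(algorithm = "perceptron",
                                           maxIter = 50, seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$trainHamming, 0L)
})

test_that("a one-chain one-position dataset behaves as a binary perceptron", {
  X <- matrix(c(1, 2), 1, 2)
  fit <- svmhmmFit(list(X), list(1L),
                   config = trainingConfig(algorithm = "perceptron",
                                           maxIter = 10, seed = 1))
  ## first pass: tie decoded as NEG, one additive update toward POS
  expect_equal(fit$W[2, ], c(1, 2))
  expect_equal(fit$W[1, ], c(-1, -2))
  expect_equal(fit$bias, c(-1, 1))
  expect_equal(fit$trainHamming, 0L)
})

test_that("training is deterministic under a fixed seed", {
  d <- separableSet(6, 15, seed = 3)
  cfg <- trainingConfig(algorithm = "perceptron", maxIter = 20, seed = 7)
  f1 <- svmhmmFit(d$X, d$y, config = cfg)
  f2 <- svmhmmFit(d$X, d$y, config = cfg)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$trans, f2$trans)

  s1 <- svmhmmFit(d$X, d$y, config = trainingConfig(maxIter = 30))
  s2 <- svmhmmFit(d$X, d$y, config = trainingConfig(maxIter = 30))
  expect_identical(s1$W, s2$W)
  expect_identical(s1$bias, s2$bias)
})

test_that("an unconverged perceptron warns and returns averaged weights", {
  set.seed(9)
  XList <- replicate(4, matrix(rnorm(30), 15, 2), simplify = FALSE)
  yList <- replicate(4, sample(0:1, 15, replace = TRUE), simplify = FALSE)
  expect_warning(
    fit <- svmhmmFit(XList, yList,
                     config = trainingConfig(algorithm = "perceptron",
                                             maxIter = 3, seed = 1)),
    "did not converge")
  expect_false(fit$converged)
})

test_that("a huge epsilon terminates the SSVM immediately with zero weights", {
  d <- separableSet(5, 10, seed = 4)
  fit <- svmhmmFit(d$X, d$y,
                   config = trainingConfig(epsilon = 1e6, maxIter = 50))
  expect_true(fit$converged)
  expect_equal(nrow(fit$trainingLog), 1L)
  expect_equal(fit$W, matrix(0, 2, 4))
})

test_that("the one-slack SSVM separates a separable set at large c", {
  d <- separableSet(10, 20, seed = 5)
  fit <- svmhmmFit(d$X, d$y,
                   config = trainingConfig(c = 10, epsilon = 0.05,
                                           maxIter = 200))
  expect_true(fit$converged)
  expect_equal(fit$trainHamming, 0L)
  log <- fit$trainingLog
  ## termination: most-violated constraint violated by at most epsilon
  expect_lte(log$violation[nrow(log)], 0.05)
  ## dual objective is non-decreasing across cutting-plane iterations
  expect_true(all(diff(log$dual) >= -1e-8))
  ## weak duality on the working-set problem
  expect_true(all(log$primal - log$dual >= -1e-8))
})

test_that("feature scaling leaves separable perceptron decisions unchanged", {
  d <- separableSet(6, 15, seed = 6)
  cfg <- trainingConfig(algorithm = "perceptron", maxIter = 50, seed = 2)
  f1 <- svmhmmFit(d$X, d$y, config = cfg)
  f2 <- svmhmmFit(lapply(d$X, function(x) 10 * x), d$y, config = cfg)
  expect_equal(f1$trainHamming, 0L)
  expect_equal(f2$trainHamming, 0L)
  m1 <- hmsvmModel(f1$W, f1$bias, f1$trans)
  m2 <- hmsvmModel(f2$W, f2$bias, f2$trans)
  for (i in seq_along(d$X))
    expect_identical(viterbiDecode(m1, d$X[[i]])$labels,
                     viterbiDecode(m2, 10 * d$X[[i]])$labels)
})

test_that("NA gold labels are excluded from the loss but kept in the chain", {
  d <- separableSet(4, 12, seed = 7)
  yNA <- lapply(d$y, function(y) {
    y[3:4] <- NA_integer_
    y
  })
  fit <- svmhmmFit(d$X, yNA,
                   config = trainingConfig(algorithm = "perceptron",
                                           maxIter = 30, seed = 1))
  expect_true(fit$converged)
})

test_that("empty training sets and bad inputs are rejected", {
  expect_error(svmhmmFit(list(), list()), "empty")
  expect_error(svmhmmFit(list(matrix(0, 3, 2)), list(c(0L, 1L))), "length")
  expect_error(trainingConfig(c = -1))
  expect_error(trainingConfig(epsilon = 0))
})
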