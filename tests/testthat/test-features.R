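test_that("percentage rows become simplex frequency rows", {
  p <- matrix(0, 1, 20, dimnames = list(NULL, aminoAcids()))
  p[1, "A"] <- 100
  expect_equal(unname(percentagesToFrequencyProfile(p, 0)[1, "A"]), 1.0)

  expect_equal(unname(percentagesToFrequencyProfile(matrix(0, 1, 20), 1)[1, ]),
               rep(1 / 20, 20))

  p[] <- 0
  p[1, "A"] <- 60
  p[1, "K"] <- 40
  f <- percentagesToFrequencyProfile(p, 0)
  expect_equal(unname(f[1, c("A", "K")]), c(0.6, 0.4))
  expect_equal(rowSums(f), 1, tolerance = 1e-12)
})

test_that("order-profile symbols follow the threshold rule with argmax fallback", {
  row <- rep(0.1 / 18, 20)
  names(row) <- aminoAcids()
  row["A"] <- 0.6
  row["K"] <- 0.3
  expect_equal(toOrderProfile(row, 0.2), "AK")

  one <- rep(0, 20)
  one[1] <- 1
  expect_equal(toOrderProfile(one, 0.5), "A")

  unif <- rep(0.05, 20)
  expect_equal(toOrderProfile(unif, 0.1), "A")
})

test_that("order-profile symbols are equivariant under amino-acid permutation", {
  set.seed(4)
  aas <- aminoAcids()
  for (rep_ in 1:20) {
    row <- rgamma(20, 1)
    row <- row / sum(row)
    perm <- sample(20)
    sym <- toOrderProfile(row, 0.15)
    symPerm <- toOrderProfile(row[order(perm)], 0.15)
    ## permuting identities maps each selected letter i to position perm[i]
    mapped <- aas[sort(perm[match(strsplit(sym, "")[[1]], aas)])]
    expect_equal(symPerm, paste(mapped, collapse = ""))
  }
})

test_that("propensity matches hand evaluation of the smoothed log-odds", {
  ## counts: interface 3x"A" + 7x"C"; surface-negative 1x"A" + 9x"C"
  ## => score("A") = log((3+1)/(10+2)) - log((1+1)/(10+2)) = log 2
  int <- symbolChain("int", c(rep("A", 3), rep("C", 7)), rep(1L, 10))
  srf <- symbolChain("srf", c("A", rep("C", 9)), rep(0L, 10))
  pt <- fitPropensityTable(ChainSet(int, srf), featureConfig())
  expect_equal(unname(pt@scores[["A"]]), log(2), tolerance = 1e-12)
  expect_equal(unname(pt@scores[["C"]]),
               log(8 / 12) - log(10 / 12), tolerance = 1e-12)
  expect_equal(pt@nInterface, 10)
  expect_equal(pt@nSurface, 10)
  ## independent scripted count of the same quantity
  cInt <- sum(c(rep("A", 3), rep("C", 7)) == "A")
  cSrf <- sum(c("A", rep("C", 9)) == "A")
  expect_equal(unname(pt@scores[["A"]]),
               log((cInt + 1) / (10 + 2)) - log((cSrf + 1) / (10 + 2)))
  ## default score is the formula at zero counts
  expect_equal(pt@defaultScore, log(1 / 12) - log(1 / 12))
})

test_that("propensity is monotone in interface and surface counts", {
  base <- list(int = c(rep("A", 3), rep("C", 7)), srf = c(rep("A", 3), rep("C", 7)))
  fit <- function(intLetters, srfLetters) {
    fitPropensityTable(ChainSet(
      symbolChain("i", intLetters, rep(1L, length(intLetters))),
      symbolChain("s", srfLetters, rep(0L, length(srfLetters)))),
      featureConfig())@scores[["A"]]
  }
  ## increasing c_int("A") at fixed totals raises the score
  s3 <- fit(c(rep("A", 3), rep("C", 7)), base$srf)
  s5 <- fit(c(rep("A", 5), rep("C", 5)), base$srf)
  s8 <- fit(c(rep("A", 8), rep("C", 2)), base$srf)
  expect_true(s3 < s5 && s5 < s8)
  ## increasing c_surf("A") at fixed totals lowers it
  t3 <- fit(base$int, c(rep("A", 3), rep("C", 7)))
  t6 <- fit(base$int, c(rep("A", 6), rep("C", 4)))
  expect_true(t6 < t3)
})

test_that("planted symbol enrichment is ranked first for a range of pseudocounts", {
  set.seed(21)
  letters_ <- c("K", "A", "C", "D", "E")
  ## interface residues enriched for "K", others uniform
  intLetters <- sample(letters_, 400, replace = TRUE,
                       prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  srfLetters <- sample(letters_, 400, replace = TRUE)
  chains <- ChainSet(symbolChain("i", intLetters, rep(1L, 400)),
                     symbolChain("s", srfLetters, rep(0L, 400)))
  for (k in c(0.1, 1, 5)) {
    pt <- fitPropensityTable(chains, featureConfig(propensityPseudocount = k))
    expect_equal(names(which.max(pt@scores)), "K", info = paste("kappa =", k))
  }
})

test_that("propensity estimation demands both classes among surface residues", {
  buried <- symbolChain("b", rep("A", 5), rep(1L, 5), asa = rep(0, 5))
  srf <- symbolChain("s", rep("C", 5), rep(0L, 5))
  expect_error(fitPropensityTable(ChainSet(buried, srf), featureConfig()),
               "at least one interface")
})

test_that("logistic PSSM scaling maps log-odds into (0,1)", {
  expect_equal(scalePssm(0), 0.5)
  expect_equal(scalePssm(12), 1 / (1 + exp(-12)), tolerance = 1e-12)
  expect_equal(scalePssm(rep(0, 20)), rep(0.5, 20))
  ## strictly inside (0,1) across the realistic PSI-BLAST log-odds range
  expect_true(all(scalePssm(-15:15) > 0 & scalePssm(-15:15) < 1))
})

test_that("relative ASA scales by nominal maxima and clips at 1.2", {
  mx <- maxASATable()
  expect_equal(relativeAsa(0, "A"), 0)
  expect_equal(relativeAsa(mx[["K"]], "K"), 1.0)
  expect_equal(relativeAsa(2 * mx[["G"]], "G"), 1.2)
  ## unknown residue types use the table mean as denominator
  expect_equal(relativeAsa(mean(mx), "X"), 1.0)
})

test_that("surface mask is boundary-inclusive", {
  expect_true(surfaceMask(0.05, 0.05))
  expect_false(surfaceMask(0.0, 0.05))
  expect_true(all(surfaceMask(c(0, 0.5, 1), 0)))
})

test_that("window encoding pads with zeros and hits D = 286 at w = 6", {
  set.seed(3)
  feat <- matrix(rnorm(5 * 22), 5, 22)
  expect_equal(encodeWindows(feat, 0), feat)

  one <- matrix(rnorm(22), 1, 22)
  enc <- encodeWindows(one, 6)
  expect_equal(ncol(enc), 286)
  expect_equal(enc[1, 6 * 22 + 1:22], one[1, ])
  expect_equal(sum(enc != 0), sum(one != 0))

  expect_error(encodeWindows(feat, -1))

  ch <- randomChain("c1", 30, seed = 8)
  pt <- fitPropensityTable(ChainSet(ch), featureConfig())
  fm <- featurizeChain(ch, featureConfig(), pt)
  expect_equal(ncol(featureValues(fm)), 286)
  fmBasic <- featurizeChain(ch, featureConfig(), featureSet = "basic")
  expect_equal(ncol(featureValues(fmBasic)), 273)
})

test_that("window encoding equals a brute-force gather and shifts correctly", {
  set.seed(13)
  feat <- matrix(rnorm(12 * 4), 12, 4)
  w <- 3
  enc <- encodeWindows(feat, w)
  for (i in 1:12) {
    expected <- unlist(lapply(-w:w, function(o) {
      j <- i + o
      if (j < 1 || j > 12) rep(0, 4) else feat[j, ]
    }))
    expect_equal(enc[i, ], expected)
  }
  ## shifting every feature row down by one shifts the whole window stencil
  shifted <- rbind(matrix(0, 1, 4), feat)
  encShift <- encodeWindows(shifted, w)
  expect_equal(encShift[2:13, ], enc)
})

test_that("featurization is deterministic", {
  ch <- randomChain("c1", 25, seed = 5)
  pt <- fitPropensityTable(ChainSet(ch), featureConfig())
  a <- featurizeChain(ch, featureConfig(), pt)
  b <- featurizeChain(ch, featureConfig(), pt)
  expect_identical(featureValues(a), featureValues(b))
})
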