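## Synthetic chain generator: clustered interface segments along the
## sequence, composition-biased frequency profiles inside interfaces, and
## elevated relative ASA at interfaces — the statistical structure the
## predictor assumes, with no external downloads.

#' Generator configuration
#'
#' Defaults emulate the broad statistics of curated complex datasets:
#' chains of 30-80 residues, contiguous interface segments covering roughly
#' a fifth to a quarter of each chain, a moderate composition bias toward an
#' interface-enriched amino-acid subset, and a moderate relative-ASA
#' elevation at interfaces.
#'
#' @param nChains Number of chains. Default 60.
#' @param lengthRange Integer (min, max) chain length. Default c(30, 80).
#' @param interfaceSegmentRate Expected interface segments per 100 residues.
#'   Default 2.5.
#' @param segmentLengthRange Integer (min, max) segment length. Default
#'   c(5, 12).
#' @param compositionShift Non-negative strength of the co-occurrence
#'   composition signal. Every position's profile mean is shifted toward a
#'   PAIR of letters from `enrichedSubset` by (base + shift * pair)/(1 +
#'   shift); at interface positions the pair is drawn within one half of
#'   the subset, elsewhere across the halves. Per-letter marginals are thus
#'   identical between classes: the signal lives in which letters co-occur
#'   at a position (an order-profile signal), not in single-letter
#'   frequencies. 0 = no composition signal. Default 0.6.
#' @param asaShift Mean relative-ASA elevation at interface residues.
#'   Default 0.25.
#' @param profileConcentration Dirichlet concentration of profile rows.
#'   Default 20.
#' @param labelNoise Label flip probability in [0, 0.5). Default 0.
#' @param enrichedSubset Interface-enriched amino acids. Default K, R, Y, W.
#' @param seed Root seed. Default 1.
#' @return A list with class `generatorConfig`.
#' @export
generatorConfig <- function(nChains = 60L, lengthRange = c(30L, 80L),
                            interfaceSegmentRate = 2.5,
                            segmentLengthRange = c(5L, 12L),
                            compositionShift = 0.6, asaShift = 0.25,
                            profileConcentration = 20, labelNoise = 0,
                            enrichedSubset = c("K", "R", "Y", "W"),
                            seed = 1L) {
  stopifnot(nChains >= 1, length(lengthRange) == 2L,
            lengthRange[1] >= 2, lengthRange[2] >= lengthRange[1],
            compositionShift == 0 || length(enrichedSubset) >= 4,
            interfaceSegmentRate >= 0,
            segmentLengthRange[1] >= 1,
            segmentLengthRange[2] >= segmentLengthRange[1],
            compositionShift >= 0, asaShift >= 0,
            profileConcentration > 0,
            labelNoise >= 0, labelNoise < 0.5,
            all(enrichedSubset %in% aminoAcids()))
  structure(list(nChains = as.integer(nChains),
                 lengthRange = as.integer(lengthRange),
                 interfaceSegmentRate = interfaceSegmentRate,
                 segmentLengthRange = as.integer(segmentLengthRange),
                 compositionShift = compositionShift,
                 asaShift = asaShift,
                 profileConcentration = profileConcentration,
                 labelNoise = labelNoise,
                 enrichedSubset = enrichedSubset,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

## Draw from an inclusive integer range (safe when lo == hi, where R's
## sample(n, ...) would instead draw from 1:n).
.sampleRange <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

## Place nSeg non-overlapping segments of the given lengths on 1..L.
## Rejection sampling; packing that cannot fit raises an error.
.placeSegments <- function(L, segLens) {
  if (length(segLens) == 0L) return(integer(0))
  if (sum(segLens) > L)
    stopData("infeasible interface segment packing: ", sum(segLens),
             " interface residues requested on a chain of length ", L)
  for (attempt in seq_len(500L)) {
    occupied <- logical(L)
    starts <- integer(length(segLens))
    ok <- TRUE
    for (s in seq_along(segLens)) {
      len <- segLens[s]
      free <- which(!vapply(seq_len(L - len + 1L),
                            function(st) any(occupied[st:(st + len - 1L)]),
                            logical(1)))
      if (length(free) == 0L) {
        ok <- FALSE
        break
      }
      st <- free[sample.int(length(free), 1L)]
      occupied[st:(st + len - 1L)] <- TRUE
      starts[s] <- st
    }
    if (ok) return(which(occupied))
  }
  stopData("could not place interface segments after 500 attempts")
}

## Integer log-odds emulation derived from the quantised percentages, so the
## PSSM feature is a deterministic function of what the files store.
.syntheticLogOdds <- function(percentages) {
  f <- (percentages + 1) / (rowSums(percentages) + 20)
  pmax(pmin(round(2 * log2(f / 0.05)), 12), -12)
}

#' Generate a synthetic labelled dataset
#'
#' Deterministic given the config seed. Interface labels form contiguous
#' segments (interfaces are sequence-clustered, which is what rewards
#' transition modelling); inside interfaces, profile rows are drawn from a
#' Dirichlet whose mean is shifted toward the enriched subset and relative
#' ASA gets a mean elevation; outside, baseline distributions. Percentages
#' are quantised to integers at generation time so that a round trip
#' through the on-disk formats reproduces the in-memory dataset exactly.
#'
#' @param config A [generatorConfig()].
#' @return A [ChainSet-class] with fully labelled chains.
#' @export
generateDataset <- function(config = generatorConfig()) {
  aas <- aminoAcids()
  baseMean <- rep(1 / 20, 20)
  ## co-occurrence pools: interface positions draw a within-pool letter
  ## pair, other positions a cross-pool pair, at equal per-letter marginals
  subs <- config$enrichedSubset
  poolA <- subs[seq_len(ceiling(length(subs) / 2))]
  poolB <- setdiff(subs, poolA)
  maxAsa <- maxASATable()
  withSeed(deriveSeed(config$seed, "generate"), {
    chains <- lapply(seq_len(config$nChains), function(cidx) {
      L <- .sampleRange(config$lengthRange[1], config$lengthRange[2])
      nSeg <- stats::rpois(1L, config$interfaceSegmentRate * L / 100)
      segLens <- if (nSeg > 0L)
        .sampleRange(config$segmentLengthRange[1],
                     config$segmentLengthRange[2], nSeg) else integer(0)
      if (config$segmentLengthRange[1] > L)
        stopData("infeasible interface segment packing: minimum segment ",
                 "length ", config$segmentLengthRange[1],
                 " exceeds chain length ", L)
      ## keep sampled segments while they fit in at most 60% of the chain,
      ## so short chains stay packable and interfaces stay a minority class
      while (length(segLens) && sum(segLens) > floor(0.6 * L))
        segLens <- segLens[-length(segLens)]
      interface <- .placeSegments(L, segLens)
      labels <- integer(L)
      labels[interface] <- 1L
      if (config$labelNoise > 0) {
        flip <- stats::runif(L) < config$labelNoise
        labels[flip] <- 1L - labels[flip]
      }
      isInt <- seq_len(L) %in% interface
      means <- matrix(rep(baseMean, each = L), L, 20)
      s <- config$compositionShift
      if (s > 0) {
        for (i in seq_len(L)) {
          pair <- if (isInt[i]) {
            pool <- if (stats::runif(1L) < 0.5) poolA else poolB
            sample(pool, 2L)
          } else {
            c(sample(poolA, 1L), sample(poolB, 1L))
          }
          pv <- as.numeric(aas %in% pair) / 2
          means[i, ] <- (baseMean + s * pv) / (1 + s)
        }
      }
      gam <- matrix(stats::rgamma(L * 20,
                                  shape = config$profileConcentration *
                                    as.vector(means)),
                    L, 20)
      prof <- gam / rowSums(gam)
      percentages <- matrix(as.integer(pmin(pmax(round(100 * prof), 0), 100)),
                            L, 20)
      colnames(percentages) <- aas
      seqAA <- vapply(seq_len(L),
                      function(i) sample(aas, 1L, prob = prof[i, ]),
                      character(1))
      rasa <- stats::rbeta(L, 2, 3)
      rasa[isInt] <- pmin(rasa[isInt] + config$asaShift, 1.19)
      asa <- round(rasa * unname(maxAsa[seqAA]), 3)
      ProteinChain(chainId = sprintf("syn%04d", cidx),
                   sequence = paste(seqAA, collapse = ""),
                   logOdds = .syntheticLogOdds(percentages),
                   percentages = percentages,
                   asa = asa,
                   labels = labels,
                   datasetType = "type_I")
    })
    ChainSet(chains)
  })
}

## ---------------------------------------------------------------------------
## On-disk rendering in exactly the dialects the readers consume.
## ---------------------------------------------------------------------------

.writePssmFile <- function(chain, path) {
  perm <- match(PSIBLAST_AA_ORDER, aminoAcids())
  lo <- chain@logOdds[, perm, drop = FALSE]
  pc <- chain@percentages[, perm, drop = FALSE]
  aa <- strsplit(chain@sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down,",
                     "information per position, and relative weight of",
                     "gapless real matches to pseudocounts")), con)
  writeLines(paste0("            ",
                    paste(sprintf("%2s", PSIBLAST_AA_ORDER), collapse = " "),
                    "   ",
                    paste(sprintf("%3s", PSIBLAST_AA_ORDER), collapse = " ")),
             con)
  for (i in seq_len(nrow(lo))) {
    writeLines(paste0(sprintf("%5d %s  ", i, aa[i]),
                      paste(sprintf("%3d", lo[i, ]), collapse = " "),
                      "  ",
                      paste(sprintf("%3d", pc[i, ]), collapse = " "),
                      "  0.00 0.00"), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3179"), con)
  invisible(path)
}

.writeFastaFile <- function(chain, path) {
  sq <- chain@sequence
  wrapped <- substring(sq, seq(1, nchar(sq), 60),
                       pmin(seq(1, nchar(sq), 60) + 59, nchar(sq)))
  writeLines(c(paste0(">", chain@chainId), wrapped), path)
  invisible(path)
}

#' Write a dataset directory
#'
#' Emits one FASTA, PSI-BLAST-style PSSM, ASA TSV and label TSV per chain,
#' plus a `manifest.yaml` and (when a generator config is given) a
#' `generator.yaml` provenance file — all in the exact dialects the package
#' readers consume, so [loadDataset()] reproduces the dataset.
#'
#' @param chains A [ChainSet-class].
#' @param dir Output directory (created if needed).
#' @param name Dataset name recorded in the manifest.
#' @param config Optional [generatorConfig()] recorded for provenance.
#' @return Invisibly, the manifest path.
#' @export
writeDataset <- function(chains, dir, name = "synthetic", config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(as.list(chains), function(ch) {
    id <- ch@chainId
    .writeFastaFile(ch, file.path(dir, paste0(id, ".fasta")))
    .writePssmFile(ch, file.path(dir, paste0(id, ".pssm")))
    writeLines(sprintf("%d\t%.3f", seq_along(ch@asa), ch@asa),
               file.path(dir, paste0(id, ".asa.tsv")))
    lab <- ch@labels
    lab[is.na(lab)] <- -1L
    writeLines(sprintf("%d\t%d", seq_along(lab), lab),
               file.path(dir, paste0(id, ".labels.tsv")))
    list(chain_id = id,
         fasta = paste0(id, ".fasta"),
         pssm = paste0(id, ".pssm"),
         asa = paste0(id, ".asa.tsv"),
         labels = paste0(id, ".labels.tsv"))
  })
  dtypes <- unique(vapply(as.list(chains), datasetType, character(1)))
  manifest <- list(name = name,
                   dataset_type = if (length(dtypes) == 1L) dtypes else "type_I",
                   entries = unname(entries))
  manifestPath <- file.path(dir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest), manifestPath)
  if (!is.null(config))
    writeLines(yaml::as.yaml(unclass(config)),
               file.path(dir, "generator.yaml"))
  invisible(manifestPath)
}

## ---------------------------------------------------------------------------
## Planted-model sampler: parameter-recovery harness.
## ---------------------------------------------------------------------------

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Sample labelled chains from a planted model
#'
#' Draws features i.i.d. standard Gaussian and samples label sequences from
#' the Gibbs distribution induced by the model's linear-chain potentials at
#' the given temperature, by exact forward filtering / backward sampling.
#' As temperature approaches 0 the samples concentrate on the Viterbi
#' labeling.
#'
#' @param model An [HMSVMModel-class] (the planted truth).
#' @param nChains Number of chains.
#' @param lengthRange Integer (min, max) chain length.
#' @param temperature Positive Gibbs temperature; 1 = the model's own scale.
#' @param seed RNG seed.
#' @return List with `X` (list of L x D matrices) and `labels` (list of
#'   integer 0/1 vectors).
#' @export
generatePlantedModelDataset <- function(model, nChains, lengthRange,
                                        temperature = 1, seed = 1L) {
  stopifnot(is(model, "HMSVMModel"))
  if (temperature <= 0) stopNumeric("temperature must be positive")
  D <- model@featureDim
  withSeed(deriveSeed(seed, "planted"), {
    X <- vector("list", nChains)
    labels <- vector("list", nChains)
    for (c_ in seq_len(nChains)) {
      L <- .sampleRange(lengthRange[1], lengthRange[2])
      Xi <- matrix(stats::rnorm(L * D), L, D)
      E <- .emissions(model@W, model@bias, Xi) / temperature
      Tt <- model@trans / temperature
      la <- matrix(0, L, 2L)
      la[1L, ] <- E[1L, ]
      if (L > 1L) for (i in 2:L) {
        la[i, 1L] <- E[i, 1L] + .logsumexp2(la[i - 1L, 1L] + Tt[1L, 1L],
                                            la[i - 1L, 2L] + Tt[2L, 1L])
        la[i, 2L] <- E[i, 2L] + .logsumexp2(la[i - 1L, 1L] + Tt[1L, 2L],
                                            la[i - 1L, 2L] + Tt[2L, 2L])
      }
      y <- integer(L)
      p2 <- 1 / (1 + exp(la[L, 1L] - la[L, 2L]))
      y[L] <- 1L + (stats::runif(1L) < p2)
      if (L > 1L) for (i in (L - 1L):1L) {
        s1 <- la[i, 1L] + Tt[1L, y[i + 1L]]
        s2 <- la[i, 2L] + Tt[2L, y[i + 1L]]
        p2 <- 1 / (1 + exp(s1 - s2))
        y[i] <- 1L + (stats::runif(1L) < p2)
      }
      X[[c_]] <- Xi
      labels[[c_]] <- y - 1L
    }
    list(X = X, labels = labels)
  })
}
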