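## Fixture builders. All fixtures are constructed in code at test time.

## A chain whose order-profile symbol at each position is exactly the given
## letter (one-hot percentage rows), with every residue on the surface.
symbolChain <- function(id, letters, labels, asa = NULL) {
  aas <- aminoAcids()
  L <- length(letters)
  pct <- matrix(0, L, 20)
  pct[cbind(seq_len(L), match(letters, aas))] <- 100
  if (is.null(asa)) asa <- rep(50, L)
  ProteinChain(id, paste(letters, collapse = ""),
               logOdds = matrix(0, L, 20), percentages = pct,
               asa = asa, labels = as.integer(labels))
}

## Write a PSI-BLAST-style ASCII PSSM fixture independently of the package
## writer. `logOdds`/`percentages` are L x 20 in PSI-BLAST column order.
writePssmFixture <- function(path, aa, logOdds, percentages,
                             order = c("A", "R", "N", "D", "C", "Q", "E",
                                       "G", "H", "I", "L", "K", "M", "F",
                                       "P", "S", "T", "W", "Y", "V")) {
  lines <- c("",
             "Last position-specific scoring matrix computed",
             paste0("            ",
                    paste(sprintf("%2s", order), collapse = " "), "   ",
                    paste(sprintf("%3s", order), collapse = " ")))
  for (i in seq_along(aa)) {
    lines <- c(lines,
               paste0(sprintf("%5d %s  ", i, aa[i]),
                      paste(sprintf("%3d", logOdds[i, ]), collapse = " "),
                      "  ",
                      paste(sprintf("%3d", percentages[i, ]), collapse = " "),
                      "  0.12 1.00"))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3179")
  writeLines(lines, path)
  path
}

## Minimal DSSP fixture: header plus fixed-column residue records with the
## amino acid at column 14 and ACC at columns 35-38.
writeDsspFixture <- function(path, aa, acc) {
  lines <- c("==== Secondary Structure Definition, synthetic fixture ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             vapply(seq_along(aa), function(i) {
               sprintf("%5d%5d %s %s%20s%4d", i, i, "A", aa[i], "", acc[i])
             }, character(1)))
  writeLines(lines, path)
  path
}

## Small fully-labelled random chain built directly in memory.
randomChain <- function(id, L, seed = 1) {
  set.seed(seed)
  aas <- aminoAcids()
  pct <- t(vapply(seq_len(L), function(i) {
    p <- rgamma(20, 1)
    as.integer(round(100 * p / sum(p)))
  }, integer(20)))
  ProteinChain(id, paste(sample(aas, L, replace = TRUE), collapse = ""),
               logOdds = matrix(sample(-5:7, L * 20, replace = TRUE), L, 20),
               percentages = pct,
               asa = runif(L, 0, 150),
               labels = as.integer(runif(L) < 0.3))
}
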