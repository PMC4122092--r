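## Amino-acid alphabets and reference tables.

#' Standard amino acids in alphabetical one-letter order
#'
#' Column order of every profile matrix held in memory by this package.
#'
#' @return Character vector of the 20 standard one-letter codes, A..Y.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## Column order PSI-BLAST prints in its ASCII matrix output.
PSIBLAST_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Nominal maximum accessible surface areas
#'
#' Rost & Sander-style nominal maximum accessible surface area (ASA) per
#' residue type, in square Angstroms. Used to convert absolute ASA values
#' (e.g. the DSSP ACC column) into relative solvent accessibility. The
#' table can be overridden wherever a `maxAsa` argument is accepted.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
maxASATable <- function() {
  c(A = 106, C = 135, D = 163, E = 194, F = 197,
    G =  84, H = 184, I = 169, K = 205, L = 164,
    M = 188, N = 157, P = 136, Q = 198, R = 248,
    S = 130, T = 142, V = 142, W = 227, Y = 222)
}
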