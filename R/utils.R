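## Internal helpers: seeded evaluation, seed derivation, config hashing.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
## Multiplication is done in 16-bit halves so every intermediate stays
## below 2^53 (exact in doubles); the XOR only touches the low byte.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- (h - lo8) + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a named sub-seed from a root seed
#'
#' All stochastic stages (data generation, fold assignment, chain shuffling)
#' draw their seed from one root seed through a named stream, so each stage
#' is independently reproducible.
#'
#' @param rootSeed Integer root seed.
#' @param stream Character name of the consuming stage.
#' @return A positive integer seed below 2^31.
#' @export
deriveSeed <- function(rootSeed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  as.integer(fnv1a32(paste0(rootSeed, ":", stream)) %% 2147483629) + 1L
}

#' Hash a configuration for provenance stamps
#'
#' @param config A list (must be YAML-serialisable).
#' @return Hex string of a 32-bit FNV-1a hash of the canonical YAML form.
#' @export
configHash <- function(config) {
  canonical <- yaml::as.yaml(config[order(names(config))])
  h <- fnv1a32(canonical)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Format doubles so that as.numeric() recovers them bit-exactly.
fmt17 <- function(x) sprintf("%.17g", x)

## Stop with a classed error so the CLI can map error families to exit codes.
stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("hmsvmPPI_data_error", "error")))
}
stopNumeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("hmsvmPPI_numeric_error", "error")))
}
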