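## Readers and writers for every external file the tool touches:
## FASTA, PSI-BLAST ASCII PSSM, ASA tables (TSV or DSSP), label tables,
## dataset manifests and the model archive.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, names = record ids
#'   (first whitespace-delimited token of each header).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stopData("FASTA file not found: ", path)
  if (file.size(path) == 0) stopData("empty FASTA file: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stopData("malformed FASTA '", path, "': ",
                                              conditionMessage(e)))
  if (length(aa) == 0L) stopData("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stopData("duplicated FASTA ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  seqs
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII matrix PSI-BLAST writes (header lines, one data row per
#' residue with 20 log-odds then 20 weighted-percentage columns, trailing
#' statistics lines). Column order is taken from the header letter line and
#' remapped to alphabetical amino-acid order; trailing per-row information
#' columns are ignored.
#'
#' @param path Path to the PSSM file.
#' @param sequence Optional sequence to cross-check residue letters against.
#' @return List with `residueIndex`, `aa` (per-residue letters), `logOdds`
#'   and `percentages` (both L x 20 matrices, alphabetical column order).
#' @export
readPssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) stopData("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  aaOrder <- NULL
  rows <- list()
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) == 0L || !nzchar(toks[1])) next
    if (is.null(aaOrder) && length(toks) %in% c(20L, 40L) &&
        all(grepl("^[A-Z]$", toks))) {
      aaOrder <- toks[1:20]
      next
    }
    if (grepl("^[0-9]+$", toks[1]) && length(toks) >= 2L &&
        grepl("^[A-ZX]$", toks[2])) {
      vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
      if (length(vals) < 40L || anyNA(vals[1:40]))
        stopData("PSSM row with fewer than 40 numeric fields at line ", ln,
                 " of ", path)
      rows[[length(rows) + 1L]] <- list(idx = as.integer(toks[1]),
                                        aa = toks[2],
                                        lo = vals[1:20], pc = vals[21:40])
    }
  }
  if (length(rows) == 0L) stopData("no PSSM data rows found in ", path)
  if (is.null(aaOrder)) aaOrder <- PSIBLAST_AA_ORDER
  perm <- match(aminoAcids(), aaOrder)
  if (anyNA(perm)) stopData("PSSM header does not list all 20 amino acids: ", path)
  idx <- vapply(rows, function(r) r$idx, integer(1))
  if (!identical(idx, seq_along(rows)))
    stopData("PSSM residue indices are not consecutive from 1 in ", path)
  lo <- t(vapply(rows, function(r) r$lo[perm], numeric(20)))
  pc <- t(vapply(rows, function(r) r$pc[perm], numeric(20)))
  if (any(pc < 0 | pc > 100))
    stopData("PSSM percentage values outside [0, 100] in ", path)
  aa <- vapply(rows, function(r) r$aa, character(1))
  if (!is.null(sequence)) {
    sq <- strsplit(toupper(sequence), "")[[1]]
    if (length(sq) != length(aa) || !all(sq == aa | aa == "X" | sq == "X"))
      stopData("PSSM residue letters disagree with the supplied sequence (",
               path, ")")
  }
  colnames(lo) <- colnames(pc) <- aminoAcids()
  list(residueIndex = idx, aa = aa, logOdds = lo, percentages = pc)
}

#' Read per-residue absolute ASA values
#'
#' Accepts a two-column TSV (1-based residue index, ASA in square Angstroms)
#' or a `.dssp` file, from which the ACC column is extracted.
#'
#' @param path Path to the ASA table.
#' @return Numeric vector of absolute ASA values, one per residue.
#' @export
readAsaTable <- function(path) {
  if (!file.exists(path)) stopData("ASA file not found: ", path)
  if (grepl("\\.dssp$", path, ignore.case = TRUE)) return(.readDsspAcc(path))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = c("integer", "numeric")),
    error = function(e) stopData("malformed ASA table '", path, "': ",
                                 conditionMessage(e)))
  if (ncol(tab) < 2L) stopData("ASA table needs two columns: ", path)
  idx <- tab[[1]]
  asa <- tab[[2]]
  if (!identical(idx, seq_len(nrow(tab))))
    stopData("ASA table indices must run 1..L without gaps: ", path)
  if (any(asa < 0)) stopData("negative ASA value in ", path)
  asa
}

## DSSP fixed-column layout: data lines follow the '  #  RESIDUE' header;
## the one-letter amino acid sits at column 14 ('!' marks chain breaks) and
## the ACC field occupies columns 35-38.
.readDsspAcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stopData("no DSSP residue header in ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  if (length(body) == 0L) stopData("no residue records in DSSP file ", path)
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(acc)) stopData("unreadable ACC field in DSSP file ", path)
  if (any(acc < 0)) stopData("negative ACC value in DSSP file ", path)
  acc
}

#' Read a per-residue label table
#'
#' Two-column TSV of (1-based residue index, label) with labels 1 =
#' interface, 0 = non-interface, -1 = unknown/excluded (returned as NA).
#'
#' @param path Path to the label table.
#' @return Integer vector over {0, 1, NA}.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stopData("label file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = c("integer", "integer")),
    error = function(e) stopData("malformed label table '", path, "': ",
                                 conditionMessage(e)))
  if (!identical(tab[[1]], seq_len(nrow(tab))))
    stopData("label table indices must run 1..L without gaps: ", path)
  lab <- tab[[2]]
  if (!all(lab %in% c(-1L, 0L, 1L)))
    stopData("labels must be -1, 0 or 1 in ", path)
  lab[lab == -1L] <- NA_integer_
  lab
}

#' Read a dataset manifest
#'
#' A YAML file with a `name` and an `entries` list; each entry names a
#' `chain_id` and the `fasta`, `pssm`, `asa` and `labels` files for that
#' chain (paths resolved relative to the manifest's directory).
#'
#' @param path Path to the manifest YAML.
#' @return List with `name`, `dataset_type` and a data.frame `entries`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopData("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  if (is.null(man$entries) || length(man$entries) == 0L)
    stopData("manifest has no entries: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  ent <- do.call(rbind, lapply(man$entries, function(e) {
    need <- c("chain_id", "fasta", "pssm", "asa", "labels")
    if (!all(need %in% names(e)))
      stopData("manifest entry missing fields (need ",
               paste(need, collapse = ", "), "): ", path)
    data.frame(chain_id = e$chain_id, fasta = resolve(e$fasta),
               pssm = resolve(e$pssm), asa = resolve(e$asa),
               labels = resolve(e$labels), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(ent$chain_id))
    stopData("duplicate chain ids in manifest: ", path)
  for (col in c("fasta", "pssm", "asa", "labels")) {
    missing <- !file.exists(ent[[col]])
    if (any(missing))
      stopData("manifest references missing ", col, " file(s) for chain(s): ",
               paste(ent$chain_id[missing], collapse = ", "))
  }
  list(name = if (is.null(man$name)) "unnamed" else man$name,
       dataset_type = if (is.null(man$dataset_type)) "type_I" else man$dataset_type,
       entries = ent)
}

#' Load a full dataset through a manifest
#'
#' Reads FASTA, PSSM, ASA and label files for every manifest entry, checks
#' that all per-chain lengths agree, and assembles a [ChainSet-class].
#' Any inconsistency fails loudly with the offending chain id.
#'
#' @param manifestPath Path to the manifest YAML.
#' @return A [ChainSet-class].
#' @export
loadDataset <- function(manifestPath) {
  man <- readManifest(manifestPath)
  chains <- lapply(seq_len(nrow(man$entries)), function(i) {
    e <- man$entries[i, ]
    fa <- readFasta(e$fasta)
    seqstr <- if (e$chain_id %in% names(fa)) fa[[e$chain_id]] else fa[[1]]
    pssm <- readPssm(e$pssm, sequence = seqstr)
    asa <- readAsaTable(e$asa)
    labels <- readLabels(e$labels)
    L <- nchar(seqstr)
    if (nrow(pssm$logOdds) != L || length(asa) != L || length(labels) != L)
      stopData("inconsistent lengths for chain ", e$chain_id,
               ": sequence ", L, ", pssm ", nrow(pssm$logOdds),
               ", asa ", length(asa), ", labels ", length(labels))
    ProteinChain(chainId = e$chain_id, sequence = seqstr,
                 logOdds = pssm$logOdds, percentages = pssm$percentages,
                 asa = asa, labels = labels,
                 datasetType = man$dataset_type)
  })
  ChainSet(chains)
}

## ---------------------------------------------------------------------------
## Model archive: a self-describing JSON file. Every double is stored as a
## "%.17g" string so the round-trip is bit-exact.
## ---------------------------------------------------------------------------

MODEL_FORMAT <- "hmsvmPPI-model"
MODEL_SCHEMA_VERSION <- 1L

.packMatrix <- function(m) list(dim = dim(m), values = fmt17(as.vector(m)))
.unpackMatrix <- function(p) matrix(as.numeric(p$values),
                                    nrow = p$dim[1], ncol = p$dim[2])

.packPropensity <- function(pt) {
  if (is.null(pt)) return(NULL)
  list(threshold = fmt17(pt@threshold),
       pseudocount = fmt17(pt@pseudocount),
       defaultScore = fmt17(pt@defaultScore),
       nInterface = fmt17(pt@nInterface),
       nSurface = fmt17(pt@nSurface),
       symbols = as.list(names(pt@scores)),
       scores = fmt17(unname(pt@scores)))
}

.unpackPropensity <- function(p) {
  if (is.null(p)) return(NULL)
  scores <- as.numeric(p$scores)
  names(scores) <- unlist(p$symbols)
  new("PropensityTable",
      threshold = as.numeric(p$threshold),
      pseudocount = as.numeric(p$pseudocount),
      scores = scores,
      defaultScore = as.numeric(p$defaultScore),
      nInterface = as.numeric(p$nInterface),
      nSurface = as.numeric(p$nSurface))
}

#' Write a model archive
#'
#' Serialises an [HMSVMModel-class] (including its propensity table and all
#' scaling/window parameters, so prediction from the archive is
#' self-contained) to a versioned JSON file. All weights survive the
#' round-trip bit-exactly.
#'
#' @param model An [HMSVMModel-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "HMSVMModel"))
  validObject(model)
  payload <- list(
    format = MODEL_FORMAT,
    schema_version = MODEL_SCHEMA_VERSION,
    featureSet = model@featureSet,
    featureDim = model@featureDim,
    windowHalf = model@windowHalf,
    labels = c("NEG", "POS"),
    W = .packMatrix(model@W),
    trans = .packMatrix(model@trans),
    bias = fmt17(model@bias),
    propensity = .packPropensity(model@propensity),
    config_yaml = yaml::as.yaml(.stripLog(model@config))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

## The training log can be large; keep the archive to configuration scalars.
.stripLog <- function(config) config[setdiff(names(config), "trainingLog")]

#' Read a model archive
#'
#' @param path Path written by [writeModel()].
#' @return The reconstructed [HMSVMModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stopData("model file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stopData("unreadable model archive '", path, "': ",
                                 conditionMessage(e)))
  if (!identical(payload$format, MODEL_FORMAT))
    stopData("not a model archive: ", path)
  if (!identical(as.integer(payload$schema_version), MODEL_SCHEMA_VERSION))
    stopData("model schema version mismatch in ", path, ": found ",
             payload$schema_version, ", supported ", MODEL_SCHEMA_VERSION)
  cfg <- tryCatch(yaml::yaml.load(payload$config_yaml),
                  error = function(e) list())
  if (is.null(cfg)) cfg <- list()
  new("HMSVMModel",
      W = .unpackMatrix(payload$W),
      trans = .unpackMatrix(payload$trans),
      bias = as.numeric(payload$bias),
      featureDim = as.integer(payload$featureDim),
      featureSet = payload$featureSet,
      windowHalf = as.integer(payload$windowHalf),
      propensity = .unpackPropensity(payload$propensity),
      config = cfg)
}
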