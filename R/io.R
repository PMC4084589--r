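#' Read protein sequences from FASTA
#'
#' Wraps Biostrings FASTA input: sequences are upper-cased, whitespace is
#' stripped, and records containing residues outside the canonical alphabet
#' are kept but flagged (see [hasNonstandard()]); the package-wide policy
#' excludes those residues from counting descriptors and property lookups.
#'
#' @param path FASTA file path.
#' @return List of [ProteinRecord-class] objects.
#' @export
readProteins <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- sub("[[:space:]].*$", "", names(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence in FASTA record '", ids[!nzchar(seqs)][1], "'")
  mapply(ProteinRecord, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records as FASTA
#' @param records list of [ProteinRecord-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteins <- function(records, path) {
  seqs <- vapply(records, proteinSequence, character(1))
  ids <- vapply(records, recordId, character(1))
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a PSI-BLAST profile written with the -Q option
#'
#' Reads the text layout produced by `blastpgp -Q` / `psiblast
#' -out_ascii_pssm`: header lines, then one row per residue carrying the
#' position index, the residue letter, 20 integer log-odds columns and 20
#' weighted-percentage columns. Columns are reordered from the file's header
#' letters (NCBI order in real files) to [aaAlphabet()].
#'
#' @param path profile file path.
#' @param block which 20-column block to return: `"logodds"` (default) or
#'   `"percent"`.
#' @return A [ProfileMatrix-class] with `source = "pssm"` and the residue
#'   column retained for cross-checks.
#' @export
readPssmProfile <- function(path, block = c("logodds", "percent")) {
  block <- match.arg(block)
  lines <- readLines(path, warn = FALSE)
  tok <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(t) t[nzchar(t)])
  headerAt <- which(vapply(tok, function(t) {
    length(t) %in% c(20L, 40L) && all(t %in% aaAlphabet())
  }, logical(1)))
  if (!length(headerAt))
    stop("not a blastpgp -Q profile: no amino-acid header line in ", path)
  headerAt <- headerAt[1]
  colOrder <- tok[[headerAt]][1:20]
  rows <- list()
  residues <- character(0)
  for (i in (headerAt + 1L):length(tok)) {
    t <- tok[[i]]
    if (!length(t)) break                       # blank line ends the table
    if (is.na(suppressWarnings(as.numeric(t[1])))) break  # K/Lambda footer
    if (length(t) < 42L)
      stop("profile format error at line ", i, ": expected at least 42 fields, got ",
           length(t), " (last good line ", i - 1L, ")")
    vals <- suppressWarnings(as.numeric(t[3:42]))
    if (any(is.na(vals)))
      stop("profile format error at line ", i, ": non-numeric score field")
    residues <- c(residues, t[2])
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("no profile rows found in ", path)
  m <- do.call(rbind, rows)
  sel <- if (block == "logodds") 1:20 else 21:40
  m <- m[, sel, drop = FALSE]
  colnames(m) <- colOrder
  m <- m[, aaAlphabet(), drop = FALSE]
  ProfileMatrix(m, source = "pssm", residues = residues)
}

#' Write a profile matrix in the blastpgp -Q text layout
#'
#' Emits the classical layout (NCBI residue-column order), so that generated
#' fixtures round-trip bit-identically through [readPssmProfile()].
#'
#' @param profile a [ProfileMatrix-class]; its residues slot (or "X") fills
#'   the residue column.
#' @param path output path.
#' @param percent optional N x 20 percentage block; zeros if omitted.
#' @return `path`, invisibly.
#' @export
writePssmProfile <- function(profile, path, percent = NULL) {
  m <- as.matrix(profile)
  n <- nrow(m)
  ncbi <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- m[, ncbi, drop = FALSE]
  if (is.null(percent)) percent <- matrix(0L, n, 20) else {
    colnames(percent) <- aaAlphabet()
    percent <- percent[, ncbi, drop = FALSE]
  }
  res <- if (length(profile@residues)) profile@residues else rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped real matches to pseudocounts",
    paste0("          ", paste(sprintf("%4s", c(ncbi, ncbi)), collapse = ""))), con)
  for (i in seq_len(n)) {
    writeLines(paste0(sprintf("%5d %s", i, res[i]),
                      paste(sprintf("%4d", as.integer(round(m[i, ]))), collapse = ""),
                      " ",
                      paste(sprintf("%4d", as.integer(round(percent[i, ]))), collapse = ""),
                      sprintf("  %4.2f %4.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3177"), con)
  invisible(path)
}

#' Extract the C-alpha backbone from a PDB file
#'
#' Returns one (x, y, z) coordinate per residue in residue order, using
#' C-alpha ATOM records only, the first model of multi-model files, and the
#' highest-occupancy alternate location when duplicates are present.
#'
#' @param path PDB file path.
#' @return M x 3 numeric matrix of coordinates.
#' @export
readBackbone <- function(path) {
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha ATOM records in ", path)
  key <- paste(at$chain, at$resno, at$insert, sep = "_")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(idx) idx[which.max(at$o[idx])]),
                 use.names = FALSE)
  keep <- sort(keep)
  coords <- as.matrix(at[keep, c("x", "y", "z")])
  dimnames(coords) <- NULL
  coords
}

#' Write C-alpha coordinates as a minimal PDB file
#'
#' One alanine C-alpha ATOM record per coordinate row; used for synthetic
#' backbone fixtures that round-trip through [readBackbone()].
#'
#' @param coords M x 3 numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBackbonePdb <- function(coords, path) {
  coords <- as.matrix(coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(coords))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, i, coords[i, 1], coords[i, 2], coords[i, 3], 1, 0), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write descriptor vectors as a delimited table
#'
#' One row per descriptor, with a header naming the descriptor tag, the
#' property accession, and the feature column indices.
#'
#' @param descriptors list of [DescriptorVector-class] objects (equal length).
#' @param path output path.
#' @param ids optional row identifiers.
#' @return `path`, invisibly.
#' @export
writeDescriptorTable <- function(descriptors, path, ids = NULL) {
  stopifnot(length(descriptors) > 0)
  dims <- vapply(descriptors, length, integer(1))
  if (length(unique(dims)) != 1L)
    stop("descriptors have differing dimensionalities")
  m <- do.call(rbind, lapply(descriptors, featureValues))
  df <- data.frame(
    id = if (is.null(ids)) seq_len(nrow(m)) else ids,
    descriptor = vapply(descriptors, descriptorId, character(1)),
    property = vapply(descriptors, propertyId, character(1)),
    m, check.names = FALSE)
  names(df)[-(1:3)] <- paste0("f", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
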