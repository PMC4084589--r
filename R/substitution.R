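#' Read a 20 x 20 substitution matrix from delimited text
#'
#' Accepts whitespace-delimited files with an optional header row of residue
#' letters and an optional leading residue column; rows/columns are reordered
#' to [aaAlphabet()] when labels are present, otherwise assumed to be in
#' alphabet order already.
#'
#' @param path path to the matrix file.
#' @param name matrix name (defaults to the file name).
#' @return A [SubstitutionMatrix-class].
#' @export
readSubstitutionMatrix <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  hasHeader <- all(is.na(suppressWarnings(as.numeric(tok[[1]]))))
  colLabels <- NULL
  if (hasHeader) {
    colLabels <- toupper(tok[[1]])
    tok <- tok[-1]
  }
  if (length(tok) != 20L)
    stop("substitution matrix must have 20 rows, found ", length(tok))
  rowLabels <- NULL
  firstIsLabel <- is.na(suppressWarnings(as.numeric(tok[[1]][1])))
  rows <- lapply(tok, function(t) {
    if (firstIsLabel) {
      rowLabels <<- c(rowLabels, toupper(t[1]))
      t <- t[-1]
    }
    v <- suppressWarnings(as.numeric(t))
    if (length(v) != 20L || any(is.na(v)))
      stop("substitution matrix row with ", length(v), " numeric values; expected 20")
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (!is.null(rowLabels)) rowLabels else aaAlphabet()
  colnames(m) <- if (!is.null(colLabels)) colLabels else aaAlphabet()
  SubstitutionMatrix(name, m[aaAlphabet(), aaAlphabet()])
}

#' Write a substitution matrix as delimited text
#' @param m a [SubstitutionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSubstitutionMatrix <- function(m, path) {
  e <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(" ", colnames(e)), collapse = " "), con)
  for (i in seq_len(20)) {
    writeLines(paste(c(rownames(e)[i], formatC(e[i, ], format = "g", digits = 8)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' The Dayhoff-family mutation matrix used by the profile construction
#'
#' Returns the classical PAM250 log-odds matrix (Dayhoff mutation data),
#' taken from the score matrices shipped with Biostrings and restricted to
#' the 20 canonical residues in [aaAlphabet()] order.
#'
#' @return A [SubstitutionMatrix-class].
#' @examples
#' dayhoffMatrix()
#' @export
dayhoffMatrix <- function() {
  env <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = env)
  m <- get("PAM250", envir = env)
  SubstitutionMatrix("PAM250", m[aaAlphabet(), aaAlphabet()])
}
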