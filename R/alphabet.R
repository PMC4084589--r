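#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order
#' (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y). Every
#' descriptor in the package uses this fixed ordering for its linear indices
#' k = j + 20 (i - 1).
#'
#' @return Character vector of length 20.
#' @examples
#' aaAlphabet()
#' @export
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Position of amino-acid symbols in the canonical alphabet
#'
#' @param symbols character vector of one-letter codes.
#' @return Integer positions in 1..20 (`NA` for nonstandard symbols).
#' @examples
#' aaIndexOf(c("A", "Y", "X"))
#' @export
aaIndexOf <- function(symbols) {
  match(toupper(symbols), aaAlphabet())
}

# Nonstandard one-letter codes occasionally seen in sequence databases.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z", "*", "-", ".")

# Three-letter -> one-letter mapping (used when converting AAindex tables).
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)

# Split a sequence string into residue characters.
splitResidues <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# Residue characters with nonstandard symbols removed (the package-wide
# policy: counting descriptors and property lookups see canonical residues
# only, and the effective length N counts canonical residues).
canonicalResidues <- function(sequence) {
  r <- splitResidues(sequence)
  r[r %in% aaAlphabet()]
}
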