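#' @import methods
NULL

#' PhysicochemicalProperty: one amino-acid index
#'
#' A named set of 20 numerical values, one per canonical amino acid, such as
#' hydrophobicity or residue volume scales from the AAindex database.
#'
#' @slot id accession string.
#' @slot values numeric vector of length 20, named by [aaAlphabet()].
#' @exportClass PhysicochemicalProperty
setClass("PhysicochemicalProperty",
  representation(id = "character", values = "numeric"),
  validity = function(object) {
    if (length(object@values) != 20L) return("values must have length 20")
    if (!identical(names(object@values), aaAlphabet()))
      return("values must be named by the canonical alphabet, in order")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  }
)

#' Construct a PhysicochemicalProperty
#'
#' @param id accession string.
#' @param values numeric vector of 20 values; if named, reordered to the
#'   canonical alphabet, otherwise assumed already in alphabet order.
#' @return A [PhysicochemicalProperty-class] object.
#' @examples
#' p <- PhysicochemicalProperty("TOY", stats::setNames(1:20, aaAlphabet()))
#' propertyStats(p)
#' @export
PhysicochemicalProperty <- function(id, values) {
  values <- as.numeric(values) |> stats::setNames(
    if (is.null(names(values))) aaAlphabet() else names(values))
  if (!is.null(names(values)) && !identical(names(values), aaAlphabet())) {
    values <- values[aaAlphabet()]
  }
  names(values) <- aaAlphabet()
  new("PhysicochemicalProperty", id = as.character(id), values = values)
}

#' SubstitutionMatrix: a 20 x 20 residue substitution matrix
#'
#' @slot name matrix name (e.g. "PAM250").
#' @slot entries 20 x 20 numeric matrix with rows/columns ordered as
#'   [aaAlphabet()].
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(name = "character", entries = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@entries), c(20L, 20L)))
      return("entries must be 20 x 20")
    if (!identical(rownames(object@entries), aaAlphabet()) ||
        !identical(colnames(object@entries), aaAlphabet()))
      return("entries must have rows and columns named by the canonical alphabet")
    TRUE
  }
)

#' Construct a SubstitutionMatrix
#'
#' @param name matrix name.
#' @param entries 20 x 20 numeric matrix; if dimnames are present the matrix
#'   is reordered to the canonical alphabet.
#' @return A [SubstitutionMatrix-class] object.
#' @export
SubstitutionMatrix <- function(name, entries) {
  entries <- as.matrix(entries)
  if (!is.null(rownames(entries)) && !identical(rownames(entries), aaAlphabet())) {
    entries <- entries[aaAlphabet(), aaAlphabet(), drop = FALSE]
  }
  dimnames(entries) <- list(aaAlphabet(), aaAlphabet())
  new("SubstitutionMatrix", name = as.character(name), entries = entries)
}

#' ProteinRecord: a protein sequence with optional label
#'
#' The stored sequence is upper-cased and may contain nonstandard residues
#' (B, J, O, U, X, Z); those are flagged and excluded from all counting
#' descriptors and property lookups, and the effective length counts
#' canonical residues only.
#'
#' @slot id identifier.
#' @slot sequence upper-case residue string.
#' @slot label optional class label (`NA_character_` if absent).
#' @exportClass ProteinRecord
setClass("ProteinRecord",
  representation(id = "character", sequence = "character", label = "character"),
  validity = function(object) {
    if (nchar(object@sequence) < 1L) return("sequence must be nonempty")
    TRUE
  }
)

#' Construct a ProteinRecord
#'
#' @param id identifier string.
#' @param sequence residue string (case-folded to upper).
#' @param label optional class label.
#' @return A [ProteinRecord-class] object.
#' @examples
#' ProteinRecord("p1", "acdcy")
#' @export
ProteinRecord <- function(id, sequence, label = NA_character_) {
  sequence <- gsub("[[:space:]]", "", toupper(as.character(sequence)))
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  new("ProteinRecord", id = as.character(id), sequence = sequence,
      label = as.character(label))
}

#' ProfileMatrix: an N x 20 per-position numeric profile
#'
#' Rows are sequence positions, columns the 20 canonical amino acids; the
#' container for the position-specific scoring matrix (PSSM) and the
#' substitution-matrix representation (SMR).
#'
#' @slot values N x 20 numeric matrix.
#' @slot source one of "pssm", "smr", "profile".
#' @slot residues optional residue characters, one per row (length 0 if
#'   unknown), kept for cross-checks against the originating sequence.
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
  representation(values = "matrix", source = "character", residues = "character"),
  validity = function(object) {
    if (ncol(object@values) != 20L) return("profile must have exactly 20 columns")
    if (nrow(object@values) < 1L) return("profile must have at least one row")
    if (length(object@residues) &&
        length(object@residues) != nrow(object@values))
      return("residues must match the number of rows")
    TRUE
  }
)

#' Construct a ProfileMatrix
#' @param values N x 20 numeric matrix.
#' @param source representation tag ("pssm", "smr", or "profile").
#' @param residues optional per-row residue characters.
#' @return A [ProfileMatrix-class] object.
#' @export
ProfileMatrix <- function(values, source = "profile", residues = character(0)) {
  values <- as.matrix(values)
  colnames(values) <- aaAlphabet()
  new("ProfileMatrix", values = values, source = source,
      residues = as.character(residues))
}

#' SquareProteinImage: a square protein matrix treated as a grayscale image
#'
#' @slot values square numeric matrix.
#' @slot source one of "pr", "dm", "wave", "image".
#' @exportClass SquareProteinImage
setClass("SquareProteinImage",
  representation(values = "matrix", source = "character"),
  validity = function(object) {
    if (nrow(object@values) != ncol(object@values))
      return("image must be square")
    TRUE
  }
)

#' Construct a SquareProteinImage
#' @param values square numeric matrix.
#' @param source representation tag.
#' @return A [SquareProteinImage-class] object.
#' @export
SquareProteinImage <- function(values, source = "image") {
  new("SquareProteinImage", values = as.matrix(values), source = source)
}

#' Scalogram: continuous-wavelet coefficients over 100 scales
#'
#' @slot values 100 x N coefficient matrix (scales in rows).
#' @slot scales numeric vector of the decomposition scales (1..100).
#' @exportClass Scalogram
setClass("Scalogram",
  representation(values = "matrix", scales = "numeric"),
  validity = function(object) {
    if (nrow(object@values) != length(object@scales))
      return("one row per scale required")
    TRUE
  }
)

#' DescriptorVector: a fixed-length numeric feature vector
#'
#' Every descriptor in the package returns this container; its length is the
#' descriptor's declared dimensionality contract.
#'
#' @slot values numeric feature vector (all finite).
#' @slot descriptorId descriptor tag (e.g. "2G", "PP", "LPQ_G").
#' @slot propertyId accession of the physicochemical property used, or
#'   `NA_character_` for property-free descriptors.
#' @exportClass DescriptorVector
setClass("DescriptorVector",
  representation(values = "numeric", descriptorId = "character",
                 propertyId = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values)))
      return("descriptor values must all be finite")
    TRUE
  }
)

#' Construct a DescriptorVector
#' @param values numeric vector.
#' @param descriptorId descriptor tag.
#' @param propertyId property accession or `NA`.
#' @return A [DescriptorVector-class] object.
#' @export
DescriptorVector <- function(values, descriptorId,
                             propertyId = NA_character_) {
  new("DescriptorVector", values = as.numeric(values),
      descriptorId = as.character(descriptorId),
      propertyId = as.character(propertyId))
}

#' EnsembleSpec: a weighted sum-rule fusion recipe
#'
#' An ordered list of (representation, descriptor, weight) components; the
#' fused score matrix is the weighted sum of the per-component classifier
#' score matrices.
#'
#' @slot components data.frame with columns `representation`, `descriptor`,
#'   `weight`.
#' @exportClass EnsembleSpec
setClass("EnsembleSpec",
  representation(components = "data.frame"),
  validity = function(object) {
    need <- c("representation", "descriptor", "weight")
    if (!all(need %in% names(object@components)))
      return("components needs columns representation, descriptor, weight")
    w <- object@components$weight
    if (any(w < 0)) return("weights must be nonnegative")
    if (!any(w > 0)) return("at least one positive weight required")
    TRUE
  }
)

#' Construct an EnsembleSpec
#' @param representation,descriptor,weight equal-length vectors describing
#'   the fusion components, in order.
#' @return An [EnsembleSpec-class] object.
#' @export
EnsembleSpec <- function(representation, descriptor, weight) {
  new("EnsembleSpec", components = data.frame(
    representation = as.character(representation),
    descriptor = as.character(descriptor),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE))
}

#' NormalizerState: per-column [0,1] scaling learned from training rows
#'
#' @slot min,max per-column minima and maxima of the training rows.
#' @exportClass NormalizerState
setClass("NormalizerState",
  representation(min = "numeric", max = "numeric"),
  validity = function(object) {
    if (length(object@min) != length(object@max))
      return("min and max must have equal length")
    TRUE
  }
)

#' EvaluationResult: metrics from a testing protocol
#'
#' @slot accuracy headline accuracy (mean over folds for cross-validation).
#' @slot auc headline one-versus-all AUC.
#' @slot perFold per-fold metrics (one row for hold-out).
#' @slot protocol "cv10" or "holdout".
#' @slot audit audit log of the row sets touched at each training stage.
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(accuracy = "numeric", auc = "numeric",
                 perFold = "data.frame", protocol = "character",
                 audit = "data.frame"))
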