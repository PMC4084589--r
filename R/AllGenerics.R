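#' Numeric feature values of a descriptor
#' @param x a [DescriptorVector-class].
#' @return Numeric vector.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "DescriptorVector", function(x) x@values)

#' Descriptor tag of a DescriptorVector
#' @param x a [DescriptorVector-class].
#' @return Character scalar.
#' @export
setGeneric("descriptorId", function(x) standardGeneric("descriptorId"))

#' @rdname descriptorId
#' @export
setMethod("descriptorId", "DescriptorVector", function(x) x@descriptorId)

#' Property accession attached to a descriptor
#' @param x a [DescriptorVector-class] or [PhysicochemicalProperty-class].
#' @return Character scalar.
#' @export
setGeneric("propertyId", function(x) standardGeneric("propertyId"))

#' @rdname propertyId
#' @export
setMethod("propertyId", "DescriptorVector", function(x) x@propertyId)

#' @rdname propertyId
#' @export
setMethod("propertyId", "PhysicochemicalProperty", function(x) x@id)

#' Per-residue property values
#' @param x a [PhysicochemicalProperty-class].
#' @return Named numeric vector of length 20.
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

#' @rdname propertyValues
#' @export
setMethod("propertyValues", "PhysicochemicalProperty", function(x) x@values)

#' Protein sequence string
#' @param x a [ProteinRecord-class].
#' @return Character scalar (upper-case residues).
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))

#' @rdname proteinSequence
#' @export
setMethod("proteinSequence", "ProteinRecord", function(x) x@sequence)

#' Record identifier
#' @param x a [ProteinRecord-class].
#' @return Character scalar.
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname recordId
#' @export
setMethod("recordId", "ProteinRecord", function(x) x@id)

#' Class label of a record
#' @param x a [ProteinRecord-class].
#' @return Character scalar (possibly `NA`).
#' @export
setGeneric("recordLabel", function(x) standardGeneric("recordLabel"))

#' @rdname recordLabel
#' @export
setMethod("recordLabel", "ProteinRecord", function(x) x@label)

#' Does a record contain nonstandard residues?
#' @param x a [ProteinRecord-class].
#' @return Logical scalar.
#' @export
setGeneric("hasNonstandard", function(x) standardGeneric("hasNonstandard"))

#' @rdname hasNonstandard
#' @export
setMethod("hasNonstandard", "ProteinRecord", function(x) {
  any(!splitResidues(x@sequence) %in% aaAlphabet())
})

#' Source tag of a matrix representation
#' @param x a [ProfileMatrix-class], [SquareProteinImage-class].
#' @return Character scalar.
#' @export
setGeneric("matrixSource", function(x) standardGeneric("matrixSource"))

#' @rdname matrixSource
#' @export
setMethod("matrixSource", "ProfileMatrix", function(x) x@source)

#' @rdname matrixSource
#' @export
setMethod("matrixSource", "SquareProteinImage", function(x) x@source)

#' @export
setMethod("as.matrix", "ProfileMatrix", function(x, ...) x@values)

#' @export
setMethod("as.matrix", "SquareProteinImage", function(x, ...) x@values)

#' @export
setMethod("as.matrix", "Scalogram", function(x, ...) x@values)

#' @export
setMethod("as.matrix", "SubstitutionMatrix", function(x, ...) x@entries)

#' Fusion components of an EnsembleSpec
#' @param x an [EnsembleSpec-class].
#' @return data.frame with representation, descriptor, weight.
#' @export
setGeneric("ensembleComponents", function(x) standardGeneric("ensembleComponents"))

#' @rdname ensembleComponents
#' @export
setMethod("ensembleComponents", "EnsembleSpec", function(x) x@components)

#' @export
setMethod("length", "DescriptorVector", function(x) length(x@values))

#' @export
setMethod("length", "ProteinRecord", function(x) {
  length(canonicalResidues(x@sequence))
})

setMethod("show", "PhysicochemicalProperty", function(object) {
  s <- propertyStats(object)
  cat("PhysicochemicalProperty", object@id,
      sprintf("(mu = %.4g, sigma = %.4g)\n", s["mu"], s["sigma"]))
})

setMethod("show", "SubstitutionMatrix", function(object) {
  cat("SubstitutionMatrix", object@name, "(20 x 20)\n")
})

setMethod("show", "ProteinRecord", function(object) {
  n <- nchar(object@sequence)
  cat("ProteinRecord", object@id, "|", n, "residues",
      if (hasNonstandard(object)) "(contains nonstandard residues)" else "",
      if (!is.na(object@label)) paste0("| label: ", object@label) else "",
      "\n")
})

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix [", object@source, "] ",
      nrow(object@values), " x 20\n", sep = "")
})

setMethod("show", "SquareProteinImage", function(object) {
  cat("SquareProteinImage [", object@source, "] side ",
      nrow(object@values), "\n", sep = "")
})

setMethod("show", "Scalogram", function(object) {
  cat("Scalogram:", nrow(object@values), "scales x",
      ncol(object@values), "positions\n")
})

setMethod("show", "DescriptorVector", function(object) {
  cat("DescriptorVector", object@descriptorId,
      if (!is.na(object@propertyId)) paste0("[", object@propertyId, "]") else "",
      "| dim", length(object@values), "\n")
})

setMethod("show", "EnsembleSpec", function(object) {
  comp <- object@components
  cat("EnsembleSpec with", nrow(comp), "components:\n")
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %g x %s(%s)\n", comp$weight[i],
                comp$representation[i], comp$descriptor[i]))
  }
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s]: accuracy %.4f, AUC %.4f (%d fold%s)\n",
              object@protocol, object@accuracy, object@auc,
              nrow(object@perFold), if (nrow(object@perFold) > 1) "s" else ""))
})
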