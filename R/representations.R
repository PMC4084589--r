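# The five matrix representations of a protein: profile-derived PSSM,
# substitution-matrix representation (SMR), physicochemical property
# response matrix (PR), Meyer-wavelet scalogram (WAVE), and the C-alpha
# distance matrix (DM), plus the per-residue property profile they share.

#' Build a PSSM from a frequency-ratio profile and a substitution matrix
#'
#' `PSSM(i, j) = sum_k w(i, k) * Y(j, k)`: each position's observed residue
#' frequencies are scored against every target residue through a
#' substitution matrix (classically Dayhoff's mutation matrix, see
#' [dayhoffMatrix()]).
#'
#' @param w N x 20 matrix of per-position frequency ratios in `[0, 1]`,
#'   columns in [aaAlphabet()] order.
#' @param Y a [SubstitutionMatrix-class].
#' @return A [ProfileMatrix-class] with `source = "pssm"`.
#' @export
buildPssmFromProfile <- function(w, Y) {
  w <- as.matrix(w)
  if (ncol(w) != 20L) stop("frequency profile must have 20 columns")
  ym <- as.matrix(Y)
  ProfileMatrix(w %*% t(ym), source = "pssm")
}

#' Substitution-matrix representation of a sequence
#'
#' Row i of the N x 20 output is the substitution-matrix row of residue
#' `p_i` — the mutation propensities of each position.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param M a [SubstitutionMatrix-class].
#' @return A [ProfileMatrix-class] with `source = "smr"`.
#' @export
buildSmr <- function(seq, M) {
  res <- canonicalResidues(asSequence(seq))
  if (!length(res)) stop("no canonical residues in sequence")
  m <- as.matrix(M)[aaIndexOf(res), , drop = FALSE]
  rownames(m) <- NULL
  ProfileMatrix(m, source = "smr", residues = res)
}

#' Physicochemical property response matrix
#'
#' `PRM(i, j) = index(p_i, d) + index(p_j, d)` — a symmetric N x N matrix of
#' pairwise property sums, treated downstream as a grayscale image. When the
#' effective sequence length exceeds `maxSide` the matrix is resized
#' (bilinear, downward only) to `maxSide` x `maxSide`.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @param maxSide resize cap (default 250).
#' @return A [SquareProteinImage-class] with `source = "pr"`.
#' @export
buildPr <- function(seq, d, maxSide = 250L) {
  pp <- featureValues(propertyProfile(seq, d))
  m <- outer(pp, pp, `+`)
  if (nrow(m) > maxSide) m <- bilinearResize(m, maxSide, maxSide)
  SquareProteinImage(m, source = "pr")
}

#' Meyer-wavelet scalogram of a property-encoded sequence
#'
#' The sequence is numerically encoded with property `d` (see
#' [propertyProfile()]) and transformed with the continuous Meyer wavelet at
#' 100 decomposition scales.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @param scales decomposition scales (default 1..100).
#' @return A [Scalogram-class] (one row per scale).
#' @export
buildWave <- function(seq, d, scales = 1:100) {
  pp <- featureValues(propertyProfile(seq, d))
  if (length(pp) < 2L) stop("wavelet representation needs at least 2 residues")
  new("Scalogram", values = meyerCwt(pp, scales), scales = as.numeric(scales))
}

#' Convert a scalogram to a square-image-compatible matrix
#'
#' For texture extraction the scalogram is treated as an image; sequences
#' longer than `maxWidth` positions are resized (bilinear) to
#' 100 x `maxWidth`, mirroring the response-matrix resize rule.
#'
#' @param scalogram a [Scalogram-class].
#' @param maxWidth width cap (default 250).
#' @return Numeric matrix.
#' @export
scalogramImage <- function(scalogram, maxWidth = 250L) {
  m <- as.matrix(scalogram)
  if (ncol(m) > maxWidth) m <- bilinearResize(m, nrow(m), maxWidth)
  m
}

#' C-alpha distance matrix
#'
#' `DM(i, j)` is the Euclidean distance between backbone coordinates i and
#' j; symmetric with zero diagonal.
#'
#' @param coords M x 3 coordinate matrix (e.g. from [readBackbone()]).
#' @return A [SquareProteinImage-class] with `source = "dm"`.
#' @export
buildDm <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("distance matrix needs at least 2 coordinates")
  m <- as.matrix(stats::dist(coords))
  dimnames(m) <- NULL
  SquareProteinImage(m, source = "dm")
}

#' Property profile of a sequence
#'
#' Element i is `index(p_i, d)`: the residue string re-encoded as the
#' numeric values of one physicochemical property. Nonstandard residues are
#' excluded, so the profile length equals the canonical-residue count.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @return A [DescriptorVector-class] of length N (tag "PPROF").
#' @export
propertyProfile <- function(seq, d) {
  res <- canonicalResidues(asSequence(seq))
  if (!length(res)) stop("no canonical residues in sequence")
  DescriptorVector(propertyValues(d)[res], "PPROF", propertyId(d))
}

# Accept either a ProteinRecord or a bare string everywhere a sequence is
# expected.
asSequence <- function(seq) {
  if (is(seq, "ProteinRecord")) proteinSequence(seq) else as.character(seq)
}
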