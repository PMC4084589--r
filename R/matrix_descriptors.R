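# Fixed-length descriptors computed from an N x 20 profile matrix (and, for
# the SVD/DCT summaries, from any rectangular matrix). Linear indices scan
# the cells as k = j + 20 (i - 1) unless a descriptor's own formula states
# otherwise.

asProfileValues <- function(Mat) {
  m <- if (is(Mat, "ProfileMatrix")) as.matrix(Mat) else as.matrix(Mat)
  if (ncol(m) != 20L) stop("a 20-column profile matrix is required")
  m
}

#' Average blocks descriptor (400 values)
#'
#' The profile is cut into 20 row blocks (each about 5% of the sequence,
#' boundaries at `round(z N / 20)`); cell (i, j) of the output is the mean
#' of column j over block i.
#'
#' @param Mat a [ProfileMatrix-class] or N x 20 matrix, N >= 20.
#' @return A [DescriptorVector-class] of length 400 (tag "AB").
#' @export
averageBlocks <- function(Mat) {
  m <- asProfileValues(Mat)
  n <- nrow(m)
  if (n < 20L) stop("average blocks needs at least 20 rows")
  bounds <- round((0:20) * n / 20)
  out <- matrix(0, 20, 20)
  for (i in 1:20) {
    rows <- (bounds[i] + 1L):bounds[i + 1L]
    out[i, ] <- colMeans(m[rows, , drop = FALSE])
  }
  DescriptorVector(as.vector(t(out)), "AB")
}

#' Single average descriptor (400 values)
#'
#' Rows of the profile are grouped by the residue at each position:
#' `SA(z, j)` is the mean of `Mat(i, j)` over positions i carrying amino
#' acid `A(z)`; rows for absent amino acids are 0. With
#' `normalize = TRUE` the profile is first passed through an elementwise
#' sigmoid `1 / (1 + exp(-x))` (the "SAN" variant).
#'
#' @param Mat a [ProfileMatrix-class] or N x 20 matrix.
#' @param seq the originating sequence (a [ProteinRecord-class] or string);
#'   its canonical residues must match the profile rows 1:1.
#' @param normalize apply the sigmoid normalization first.
#' @return A [DescriptorVector-class] of length 400 (tag "SA" or "SAN").
#' @export
singleAverage <- function(Mat, seq, normalize = FALSE) {
  m <- asProfileValues(Mat)
  idx <- residueIndices(seq)
  if (length(idx) != nrow(m))
    stop("sequence length (", length(idx), ") does not match profile rows (",
         nrow(m), ")")
  if (normalize) m <- 1 / (1 + exp(-m))
  out <- matrix(0, 20, 20)
  for (z in 1:20) {
    rows <- which(idx == z)
    if (length(rows)) out[z, ] <- colMeans(m[rows, , drop = FALSE])
  }
  DescriptorVector(as.vector(t(out)), if (normalize) "SAN" else "SA")
}

#' Matrix autocovariance descriptor (300 values)
#'
#' For each column j and lag 1..15, the average product of the deviations
#' from the column mean at positions i and i + lag, normalized by
#' (N - lag); `k = j + 20 (lag - 1)`.
#'
#' @param Mat a [ProfileMatrix-class] or N x 20 matrix, N > 15.
#' @param lagMax maximum lag (default 15).
#' @return A [DescriptorVector-class] of length 20 * lagMax (tag "AM").
#' @export
autocovarianceMatrix <- function(Mat, lagMax = 15L) {
  m <- asProfileValues(Mat)
  n <- nrow(m)
  if (n <= lagMax) stop("matrix autocovariance needs more than ", lagMax, " rows")
  dev <- sweep(m, 2, colMeans(m))
  out <- matrix(0, lagMax, 20)
  for (lag in seq_len(lagMax)) {
    out[lag, ] <- colSums(dev[1:(n - lag), , drop = FALSE] *
                            dev[(1 + lag):n, , drop = FALSE]) / (n - lag)
  }
  DescriptorVector(as.vector(t(out)), "AM")
}

#' Pseudo-PSSM descriptor (320 values)
#'
#' The profile is row-standardized (each row centered on its mean and
#' scaled by its dispersion; the default scales by the standard deviation,
#' `strict = TRUE` reproduces the unsquare-rooted printed normalization).
#' The first 20 entries are the column means of the standardized matrix;
#' the remaining 300 are, for each column and lag 1..15, the mean squared
#' difference between entries lag rows apart, at
#' `k = 20 + j + 20 (lag - 1)`. Zero-variance rows standardize to zero
#' rows, with a warning.
#'
#' @param Mat a [ProfileMatrix-class] or N x 20 matrix, N > 15.
#' @param lagMax maximum lag (default 15).
#' @param strict use the printed (variance, not standard-deviation)
#'   denominator.
#' @return A [DescriptorVector-class] of length 20 + 20 * lagMax (tag "PP").
#' @export
pseudoPssm <- function(Mat, lagMax = 15L, strict = FALSE) {
  m <- asProfileValues(Mat)
  n <- nrow(m)
  if (n <= lagMax) stop("pseudo-PSSM needs more than ", lagMax, " rows")
  rowMu <- rowMeans(m)
  dev <- m - rowMu
  rowVar <- rowMeans(dev^2)
  denom <- if (strict) rowVar else sqrt(rowVar)
  E <- dev
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) standardized to zero")
    E[zero, ] <- 0
  }
  E[!zero, ] <- dev[!zero, , drop = FALSE] / denom[!zero]
  head20 <- colMeans(E)
  out <- matrix(0, lagMax, 20)
  for (lag in seq_len(lagMax)) {
    out[lag, ] <- colSums((E[1:(n - lag), , drop = FALSE] -
                             E[(1 + lag):n, , drop = FALSE])^2) / (n - lag)
  }
  DescriptorVector(c(head20, as.vector(t(out))), "PP")
}

#' Singular-value descriptor
#'
#' The ordered (descending) singular values of any rectangular matrix,
#' optionally zero-padded to a declared fixed length so that descriptors
#' from matrices of different sizes align in a feature table.
#'
#' @param Mat a matrix, [ProfileMatrix-class] or [SquareProteinImage-class].
#' @param padTo optional fixed output length (>= min(dim)).
#' @return A [DescriptorVector-class] (tag "SVD").
#' @export
svdDescriptor <- function(Mat, padTo = NULL) {
  m <- as.matrix(Mat)
  if (!length(m)) stop("empty matrix")
  d <- sort(svd(m)$d, decreasing = TRUE)
  if (!is.null(padTo)) {
    if (padTo < length(d)) stop("padTo smaller than the number of singular values")
    d <- c(d, numeric(padTo - length(d)))
  }
  DescriptorVector(d, "SVD")
}

#' Discrete-cosine descriptor (400 values)
#'
#' The 2-D orthonormal DCT-II of the matrix (zero-padded to at least
#' 20 x 20 if smaller), retaining the low-frequency top-left 20 x 20
#' coefficient block in row-major order.
#'
#' @param Mat a matrix, [ProfileMatrix-class] or [SquareProteinImage-class].
#' @return A [DescriptorVector-class] of length 400 (tag "DCT").
#' @export
dctDescriptor <- function(Mat) {
  m <- as.matrix(Mat)
  if (nrow(m) < 20L || ncol(m) < 20L) {
    pad <- matrix(0, max(20L, nrow(m)), max(20L, ncol(m)))
    pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- pad
  }
  D <- dct2(m)
  DescriptorVector(as.vector(t(D[1:20, 1:20])), "DCT")
}

#' Profile n-gram descriptors (400 + 8000 values)
#'
#' Accumulates soft n-gram frequencies directly from the profile:
#' `BGR(l) = sum_z Mat(z, i) Mat(z+1, j)` at `l = (i - 1) 20 + j`, and
#' `TGR(l) = sum_z Mat(z, i) Mat(z+1, j) Mat(z+2, k)` at
#' `l = (i - 1) 400 + (j - 1) 20 + k`.
#'
#' @param Mat a [ProfileMatrix-class] or N x 20 matrix, N >= 3.
#' @return List with elements `bgr` (length 400) and `tgr` (length 8000),
#'   both [DescriptorVector-class].
#' @export
ngramMatrix <- function(Mat) {
  m <- asProfileValues(Mat)
  n <- nrow(m)
  if (n < 3L) stop("profile n-grams need at least 3 rows")
  B <- t(m[1:(n - 1), , drop = FALSE]) %*% m[2:n, , drop = FALSE]
  Tarr <- array(0, c(20, 20, 20))
  for (z in 1:(n - 2)) {
    Tarr <- Tarr + outer(m[z, ], outer(m[z + 1, ], m[z + 2, ]))
  }
  # l = (i-1)*400 + (j-1)*20 + k: k fastest, then j, then i
  tgr <- as.vector(aperm(Tarr, c(3, 2, 1)))
  list(bgr = DescriptorVector(as.vector(t(B)), "BGR"),
       tgr = DescriptorVector(tgr, "TGR"))
}
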