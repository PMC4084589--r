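# Fixed-length descriptors computed directly from the amino-acid sequence.
# All use the canonical-residue policy (nonstandard residues excluded, the
# effective length N counts canonical residues) and the fixed linear index
# k = j + 20 (i - 1) over the alphabetical residue ordering.

# residue index vector (1..20) for the canonical residues of a sequence
residueIndices <- function(seq) {
  res <- canonicalResidues(asSequence(seq))
  if (!length(res)) stop("no canonical residues in sequence")
  aaIndexOf(res)
}

# 20 x 20 count matrix of ordered residue pairs at distance m
pairCounts <- function(idx, m = 1L) {
  n <- length(idx)
  h <- matrix(0, 20, 20)
  if (n > m) {
    tab <- table(factor(idx[1:(n - m)], levels = 1:20),
                 factor(idx[(1 + m):n], levels = 1:20))
    h <- matrix(as.numeric(tab), 20, 20)
  }
  h
}

#' Amino-acid composition (20 values)
#'
#' `AS(i) = h(i) / N`: the fraction of each canonical amino acid.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @return A [DescriptorVector-class] of length 20 (tag "AS").
#' @examples
#' featureValues(aacDescriptor("ACDC"))
#' @export
aacDescriptor <- function(seq) {
  idx <- residueIndices(seq)
  h <- tabulate(idx, nbins = 20)
  DescriptorVector(h / length(idx), "AS")
}

#' 2-gram composition (400 values)
#'
#' `2G(k) = h(i, j) / N` at `k = j + 20 (i - 1)`, counting ordered residue
#' couples at adjacent positions.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @return A [DescriptorVector-class] of length 400 (tag "2G").
#' @export
twoGramDescriptor <- function(seq) {
  idx <- residueIndices(seq)
  if (length(idx) < 2L) stop("2-gram descriptor needs at least 2 residues")
  h <- pairCounts(idx, 1L)
  DescriptorVector(as.vector(t(h)) / length(idx), "2G")
}

#' Quasi-residue couple (1200 values)
#'
#' For each order m = 1, 2, 3 and each ordered couple (i, j), accumulates
#' `index(i, d) + index(j, d)` over positions n with `p_n = i` and
#' `p_(n+m) = j`, normalized by (N - m); the three 400-long blocks are
#' concatenated.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @return A [DescriptorVector-class] of length 1200 (tag "QRC").
#' @export
qrcDescriptor <- function(seq, d) {
  idx <- residueIndices(seq)
  n <- length(idx)
  if (n <= 3L) stop("quasi-residue couple needs at least 4 residues")
  v <- propertyValues(d)
  pairValue <- outer(v, v, `+`)           # index(i,d) + index(j,d)
  blocks <- lapply(1:3, function(m) {
    h <- pairCounts(idx, m)
    as.vector(t(h * pairValue)) / (n - m)
  })
  DescriptorVector(unlist(blocks), "QRC", propertyId(d))
}

#' Autocovariance pseudo-amino-acid descriptor (20 + m values)
#'
#' The 20 amino-acid composition values followed by `m` sequence-order
#' terms: for lag l = 1..m, the mean product of centered property values at
#' positions k and k + l, scaled by the property's dispersion (see
#' [propertyStats()]).
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @param m maximum lag (default 20).
#' @param sd use the square-rooted dispersion instead of the printed mean
#'   squared deviation.
#' @return A [DescriptorVector-class] of length 20 + m (tag "AC").
#' @export
autocovarianceDescriptor <- function(seq, d, m = 20L, sd = FALSE) {
  idx <- residueIndices(seq)
  n <- length(idx)
  if (n <= m) stop("autocovariance needs sequence length > m = ", m)
  st <- propertyStats(d, sd = sd)
  if (st["sigma"] == 0)
    stop("degenerate property '", propertyId(d), "': zero dispersion")
  x <- propertyValues(d)[idx] - st["mu"]
  lags <- vapply(seq_len(m), function(l) {
    sum(x[1:(n - l)] * x[(1 + l):n]) / (st["sigma"] * (n - l))
  }, numeric(1))
  DescriptorVector(c(featureValues(aacDescriptor(seq)), lags), "AC",
                   propertyId(d))
}

#' AAIndexLoc descriptor (65 values)
#'
#' Concatenation of: amino-acid composition (20), the composition weighted
#' by the property value of each residue (20), and a 5 x 5 dipeptide
#' composition over a five-group k-means clustering of the 20 property
#' values (25). Groups are relabeled by ascending group minimum so the
#' grouping is deterministic; the dipeptide block is normalized by (N - 1).
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @param seed seed for the k-means restarts (default 1).
#' @return A [DescriptorVector-class] of length 65 (tag "AA").
#' @export
aaindexLocDescriptor <- function(seq, d, seed = 1L) {
  idx <- residueIndices(seq)
  n <- length(idx)
  if (n < 2L) stop("AAIndexLoc needs at least 2 residues")
  v <- propertyValues(d)
  if (length(unique(v)) < 5L)
    stop("property '", propertyId(d), "' has fewer than 5 distinct values; ",
         "five-group clustering is degenerate")
  km <- withSeed(seed, stats::kmeans(matrix(v, ncol = 1), centers = 5L,
                                     nstart = 100L))
  grp <- km$cluster
  # relabel groups by ascending group-minimum property value
  mins <- vapply(1:5, function(g) min(v[grp == g]), numeric(1))
  relabel <- match(seq_len(5L), order(mins))
  grp <- relabel[grp]
  comp <- featureValues(aacDescriptor(seq))
  weighted <- comp * v
  g <- grp[idx]
  counts <- table(factor(g[1:(n - 1)], levels = 1:5),
                  factor(g[2:n], levels = 1:5))
  dip <- as.vector(t(matrix(as.numeric(counts), 5, 5))) / (n - 1)
  DescriptorVector(c(comp, weighted, dip), "AA", propertyId(d))
}

# Six physicochemical classes used by the global encoding.
GE_CLASSES <- list(
  A1 = c("A", "V", "L", "I", "M", "C"),
  A2 = c("F", "W", "Y", "H"),
  A3 = c("S", "T", "N", "Q"),
  A4 = c("K", "R"),
  A5 = c("D", "E"),
  A6 = c("G", "P"))

#' Global encoding descriptor
#'
#' The sequence is mapped onto six physicochemical classes; each of the 10
#' distinct partitions of the six classes into two three-class subsets
#' yields a binary characteristic sequence, from which four measures are
#' taken: frequency of 0s, frequency of 1s, and the 0-to-1 and 1-to-0
#' transition frequencies. With `depth > 1` the measures are recomputed on
#' nested halves of the sequence (depth levels of binary segmentation),
#' giving `40 * (2^depth - 1)` values; the default depth 1 gives 40.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param depth segmentation depth (default 1).
#' @return A [DescriptorVector-class] (tag "GE").
#' @export
globalEncodingDescriptor <- function(seq, depth = 1L) {
  res <- canonicalResidues(asSequence(seq))
  if (length(res) < 2L) stop("global encoding needs at least 2 residues")
  classOf <- integer(20)
  for (g in seq_along(GE_CLASSES)) classOf[aaIndexOf(GE_CLASSES[[g]])] <- g
  cls <- classOf[aaIndexOf(res)]
  partitions <- globalEncodingPartitions()
  measures <- function(segment) {
    unlist(lapply(partitions, function(first) {
      b <- as.integer(cls[segment] %in% first)
      len <- length(b)
      f1 <- sum(b) / len
      if (len > 1L) {
        d <- diff(b)
        t01 <- sum(d == 1) / (len - 1)
        t10 <- sum(d == -1) / (len - 1)
      } else t01 <- t10 <- 0
      c(1 - f1, f1, t01, t10)
    }))
  }
  segments <- list(seq_along(cls))
  if (depth > 1L) {
    level <- segments
    for (l in 2:depth) {
      level <- unlist(lapply(level, function(s) {
        half <- length(s) %/% 2L
        list(s[seq_len(half)], s[(half + 1L):length(s)])
      }), recursive = FALSE)
      segments <- c(segments, level)
    }
  }
  DescriptorVector(unlist(lapply(segments, measures)), "GE")
}

#' The 10 two-subset partitions of the six global-encoding classes
#'
#' Each partition splits classes 1..6 into two subsets of three; the
#' partition is identified by the subset containing class 1.
#'
#' @return List of 10 integer vectors (the "first" subsets).
#' @export
globalEncodingPartitions <- function() {
  combos <- utils::combn(6, 3)
  keep <- combos[, combos[1, ] == 1, drop = FALSE]
  lapply(seq_len(ncol(keep)), function(i) keep[, i])
}

#' Physicochemical 2-grams (800 values)
#'
#' For each ordered couple (i, j) the pair
#' `(h(i,j) index(i,d) / (N-1), h(i,j) index(j,d) / (N-1))`; couples are
#' scanned with `k = j + 20 (i - 1)` and the two members of each pair are
#' interleaved (first the i-weighted value, then the j-weighted value).
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @return A [DescriptorVector-class] of length 800 (tag "P2G").
#' @export
p2gDescriptor <- function(seq, d) {
  idx <- residueIndices(seq)
  n <- length(idx)
  if (n < 2L) stop("physicochemical 2-grams need at least 2 residues")
  v <- propertyValues(d)
  h <- pairCounts(idx, 1L)
  first <- h * matrix(v, 20, 20) / (n - 1)        # h(i,j) * index(i,d)
  second <- h * matrix(v, 20, 20, byrow = TRUE) / (n - 1)  # h(i,j) * index(j,d)
  out <- numeric(800)
  out[seq(1, 799, by = 2)] <- as.vector(t(first))
  out[seq(2, 800, by = 2)] <- as.vector(t(second))
  DescriptorVector(out, "P2G", propertyId(d))
}

# Reduced amino-acid alphabets for the n-gram descriptor, in their
# published group order. A1/A2 use 2-grams, A3/A4/A5 use 3-grams.
NG_ALPHABETS <- list(
  A1 = list(groups = as.list(c("G", "I", "V", "F", "Y", "W", "A", "L", "M", "E",
                               "Q", "R", "K", "P", "N", "D", "H", "S", "T", "C")),
            n = 2L),
  A2 = list(groups = list(c("L", "V", "I", "M"), "C", "A", "G", "S", "T", "P",
                          c("F", "Y"), "W", "E", "D", "N", "Q", c("K", "R"), "H"),
            n = 2L),
  A3 = list(groups = list(c("L", "V", "I", "M", "C"), c("A", "G"), c("S", "T"),
                          "P", c("F", "Y", "W"), c("E", "D", "N", "Q"),
                          c("K", "R"), "H"),
            n = 3L),
  A4 = list(groups = list(c("L", "V", "I", "M", "C"), c("A", "S", "G", "T", "P"),
                          c("F", "Y", "W"), c("E", "D", "N", "Q"),
                          c("K", "R", "H")),
            n = 3L),
  A5 = list(groups = list(c("L", "V", "I", "M", "C"), c("A", "S", "G", "T", "P"),
                          c("F", "Y", "W"), c("E", "D", "N", "Q", "K", "R", "H")),
            n = 3L))

#' Reduced-alphabet n-gram composition
#'
#' Translates the sequence into group symbols of one of five reduced
#' alphabets and counts n-gram occurrence frequencies (normalized by N):
#' 2-grams for alphabets A1 (20 groups, dim 400) and A2 (15, dim 225),
#' 3-grams for A3 (8, dim 512), A4 (5, dim 125) and A5 (4, dim 64).
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param alphabet one of "A1".."A5".
#' @return A [DescriptorVector-class] (tag "NG-<alphabet>").
#' @export
ngramDescriptor <- function(seq, alphabet = c("A1", "A2", "A3", "A4", "A5")) {
  alphabet <- match.arg(alphabet)
  spec <- NG_ALPHABETS[[alphabet]]
  ngroups <- length(spec$groups)
  n <- spec$n
  groupOf <- integer(20)
  for (g in seq_len(ngroups)) groupOf[aaIndexOf(spec$groups[[g]])] <- g
  idx <- residueIndices(seq)
  len <- length(idx)
  if (len < n) stop("sequence too short for ", n, "-grams")
  g <- groupOf[idx]
  counts <- numeric(ngroups^n)
  if (n == 2L) {
    lin <- (g[1:(len - 1)] - 1) * ngroups + g[2:len]
  } else {
    lin <- (g[1:(len - 2)] - 1) * ngroups^2 + (g[2:(len - 1)] - 1) * ngroups +
      g[3:len]
  }
  tab <- tabulate(lin, nbins = ngroups^n)
  DescriptorVector(tab / len, paste0("NG-", alphabet))
}

#' Split amino-acid composition (60 values)
#'
#' Amino-acid composition computed separately on the 20 N-terminal
#' residues, the region between the termini, and the 20 C-terminal
#' residues, concatenated. For sequences shorter than 41 residues the
#' termini are truncated to the available residues (and may overlap) and an
#' empty middle region encodes as zeros.
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @return A [DescriptorVector-class] of length 60 (tag "SAC").
#' @export
sacDescriptor <- function(seq) {
  res <- canonicalResidues(asSequence(seq))
  n <- length(res)
  if (n < 2L) stop("split composition needs at least 2 residues")
  compOf <- function(positions) {
    if (!length(positions)) return(numeric(20))
    featureValues(aacDescriptor(paste(res[positions], collapse = "")))
  }
  nterm <- seq_len(min(20L, n))
  cterm <- seq.int(max(1L, n - 19L), n)
  middle <- if (n >= 41L) 21L:(n - 20L) else integer(0)
  DescriptorVector(c(compOf(nterm), compOf(middle), compOf(cterm)), "SAC")
}

#' Discrete-wavelet descriptor (52 values)
#'
#' The property profile of the sequence is decomposed with a four-level
#' biorthogonal 3.3 discrete wavelet (symmetric padding); each level
#' contributes the first five discrete-cosine coefficients of its
#' approximation plus max/min/mean/standard deviation of both approximation
#' and detail coefficients (13 per level, 52 total).
#'
#' @param seq a [ProteinRecord-class] or residue string.
#' @param d a [PhysicochemicalProperty-class].
#' @return A [DescriptorVector-class] of length 52 (tag "DW").
#' @export
discreteWaveletDescriptor <- function(seq, d) {
  pp <- featureValues(propertyProfile(seq, d))
  if (length(pp) < 16L)
    stop("discrete-wavelet descriptor needs at least 16 residues")
  dec <- bior33Dwt(pp, levels = 4L)
  feats <- unlist(lapply(1:4, function(l) {
    ca <- dec$approx[[l]]
    cd <- dec$detail[[l]]
    c(dct1(ca)[1:5],
      max(ca), min(ca), mean(ca), stats::sd(ca),
      max(cd), min(cd), mean(cd), stats::sd(cd))
  }))
  DescriptorVector(feats, "DW", propertyId(d))
}
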