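# Seeded generators for every input the toolkit consumes: random protein
# sequences, profile matrices mimicking PSI-BLAST output, toy backbones,
# and labelled two-class datasets with matched synthetic profiles. All are
# pure functions of (parameters, seed).

#' Random protein sequence
#'
#' Residues sampled independently from a weight vector over the 20
#' canonical amino acids.
#'
#' @param length sequence length (>= 1).
#' @param weights nonnegative weights over [aaAlphabet()] (normalized
#'   internally); default uniform.
#' @param seed integer seed.
#' @param id record identifier.
#' @param label optional class label.
#' @return A [ProteinRecord-class].
#' @export
randomProtein <- function(length, weights = rep(1, 20), seed = 1L,
                          id = "synthetic", label = NA_character_) {
  if (length < 1L) stop("length must be >= 1")
  weights <- as.numeric(weights)
  if (length(weights) != 20L || any(weights < 0) || sum(weights) == 0)
    stop("weights must be 20 nonnegative values with positive sum")
  res <- withSeed(seed,
    sample(aaAlphabet(), length, replace = TRUE, prob = weights / sum(weights)))
  ProteinRecord(id, paste(res, collapse = ""), label)
}

#' Random profile matrix
#'
#' `mode = "frequency"`: rows are nonnegative and sum to 1 (Dirichlet-like
#' by normalized uniforms). `mode = "log_odds"`: integer entries in
#' `[-10, 10]` mimicking blastpgp output.
#'
#' @param N number of rows.
#' @param mode `"log_odds"` or `"frequency"`.
#' @param seed integer seed.
#' @return A [ProfileMatrix-class].
#' @export
randomProfileMatrix <- function(N, mode = c("log_odds", "frequency"),
                                seed = 1L) {
  mode <- match.arg(mode)
  if (N < 1L) stop("N must be >= 1")
  m <- withSeed(seed, {
    if (mode == "frequency") {
      raw <- matrix(stats::runif(N * 20), N, 20)
      raw / rowSums(raw)
    } else {
      matrix(sample(-10:10, N * 20, replace = TRUE), N, 20)
    }
  })
  ProfileMatrix(m, source = "pssm")
}

#' Toy backbone coordinates
#'
#' `"line"`: collinear points at unit spacing along x. `"helix"`: an ideal
#' alpha-helix spiral (rise 1.5 per residue, radius 2.3, 3.6 residues per
#' turn).
#'
#' @param M number of residues (>= 2).
#' @param geometry `"line"` or `"helix"`.
#' @param seed unused for these deterministic geometries; kept so all
#'   generators share a signature.
#' @return M x 3 coordinate matrix.
#' @export
toyBackbone <- function(M, geometry = c("line", "helix"), seed = 1L) {
  geometry <- match.arg(geometry)
  if (M < 2L) stop("backbone needs at least 2 residues")
  i <- seq_len(M) - 1
  if (geometry == "line") {
    cbind(i, 0, 0)
  } else {
    theta <- 2 * pi * i / 3.6
    cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  }
}

# synthetic profile coherent with a sequence: scaled one-hot rows plus
# seeded integer noise, clipped to the blastpgp log-odds range
syntheticProfileFor <- function(record, seed) {
  idx <- aaIndexOf(canonicalResidues(proteinSequence(record)))
  n <- length(idx)
  m <- matrix(0, n, 20)
  m[cbind(seq_len(n), idx)] <- 10
  noise <- withSeed(seed, matrix(sample(-3:3, n * 20, replace = TRUE), n, 20))
  ProfileMatrix(clamp(m + noise, -10, 10), source = "pssm",
                residues = aaAlphabet()[idx])
}

#' Labelled two-class synthetic dataset
#'
#' Generates `nPerClass` proteins per class with class-dependent residue
#' composition biases, plus (optionally) a matched synthetic profile per
#' record (scaled one-hot encoding of the sequence with seeded integer
#' noise in `[-3, 3]`, clipped to `[-10, 10]`), so sequence- and
#' matrix-descriptor pipelines see consistent class signal.
#'
#' `bias = "disjoint"` draws class A uniformly from the first ten amino
#' acids and class B from the last ten (disjoint composition supports);
#' `bias = "none"` gives both classes the uniform composition (a null
#' dataset). A list of two custom weight vectors is also accepted.
#'
#' @param nPerClass samples per class.
#' @param lengthRange inclusive range of sequence lengths (min >= 16).
#' @param bias `"disjoint"`, `"none"`, or list of two weight vectors.
#' @param seed integer seed.
#' @param profiles also generate matched synthetic profiles.
#' @return List with `records`, `labels` (factor "A"/"B"), and `profiles`
#'   (list of [ProfileMatrix-class] or `NULL`).
#' @export
twoClassDataset <- function(nPerClass = 100L, lengthRange = c(60L, 100L),
                            bias = "disjoint", seed = 1L, profiles = TRUE) {
  if (lengthRange[1] < 16L) stop("minimum length must be >= 16")
  weightsFor <- if (is.list(bias)) {
    if (length(bias) != 2L) stop("bias list must have two weight vectors")
    bias
  } else if (identical(bias, "disjoint")) {
    list(c(rep(1, 10), rep(0, 10)), c(rep(0, 10), rep(1, 10)))
  } else if (identical(bias, "none")) {
    list(rep(1, 20), rep(1, 20))
  } else stop("bias must be 'disjoint', 'none', or a list of two weight vectors")
  records <- list()
  profs <- list()
  labels <- character(0)
  k <- 0L
  for (cl in 1:2) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      subseed <- (seed * 1000L + k) %% .Machine$integer.max
      len <- withSeed(subseed,
        sample(lengthRange[1]:lengthRange[2], 1L))
      rec <- randomProtein(len, weightsFor[[cl]], seed = subseed + 1L,
                           id = sprintf("class%s_%03d", LETTERS[cl], i),
                           label = LETTERS[cl])
      records[[k]] <- rec
      labels <- c(labels, LETTERS[cl])
      if (profiles) profs[[k]] <- syntheticProfileFor(rec, subseed + 2L)
    }
  }
  list(records = records, labels = factor(labels),
       profiles = if (profiles) profs else NULL)
}
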