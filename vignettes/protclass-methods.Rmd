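---
title: "Protein descriptors and sum-rule SVM ensembles with protclass"
author: "protclass authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein descriptors and sum-rule SVM ensembles with protclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protclass)
```

## The problem

Sequence-based protein classification — subcellular localization,
DNA-binding prediction, fold recognition, virulence prediction — needs a
*fixed-length* numeric representation of a variable-length residue string
before any standard classifier can be applied. protclass implements a
catalogue of such representations at three levels:

1. **Representations**: the raw sequence (AAS); the position-specific
   scoring matrix (PSSM), an N × 20 profile of per-position conservation
   scores from an iterative similarity search; the substitution-matrix
   representation (SMR), whose row *i* is the substitution-matrix row of
   residue *p~i~*; the physicochemical response matrix
   PRM^d^(i, j) = index(p~i~, d) + index(p~j~, d); a continuous-wavelet
   scalogram (WAVE) of the property-encoded sequence; and the Cα
   distance matrix (DM) from the tertiary structure.
2. **Descriptors**: fixed-length vectors computed from a representation —
   compositions and n-grams, pseudo-amino-acid/autocovariance features,
   pseudo-PSSM, average blocks, soft profile n-grams, SVD/DCT summaries,
   and image-texture codes (LBP histogram Fourier, local phase
   quantization) on matrices treated as grayscale images.
3. **Classification**: one RBF-kernel SVM (libsvm, via e1071) per
   descriptor, with features linearly normalized to [0, 1] *on the
   training rows only* and hyperparameters grid-searched on the training
   rows only; classifiers are combined by a weighted sum of their
   per-class scores. The flagship recipe `fus1Spec()` fuses eight
   components — 2 × AAS(AC) + 2 × PSSM(SAN) + 4 × PSSM(PP) + PSSM(LHF_G)
   + PSSM(BGR) + PSSM(TGR) + SMR(PP) + SMR(BGR) — and `fus2Spec()` adds
   2 × DM(LPQ_G) when backbone coordinates are available.

## Conventions that everything else depends on

* **Alphabet and indices.** The 20 canonical residues are fixed in
  alphabetical one-letter order (`aaAlphabet()`); every 400-cell
  descriptor scans residue pairs with the linear index
  k = j + 20 (i − 1). Internal code is 1-based R; the documented mapping
  to 0-based formulations is the identity shift.
* **Nonstandard residues** (B, J, O, U, X, Z) are excluded from all
  counting descriptors and property lookups; the effective length N
  counts canonical residues only. This keeps every normalization
  (divisions by N, N − 1, N − lag) well defined without inventing
  values the property tables do not contain.
* **Properties.** An amino-acid index is 20 numeric values; the built-in
  table (`aaindexProperties()`, from the seqinr copy of the AAindex
  database, 544 entries) drops entries with missing values and indicator
  entries whose values are all 0 or 1. The dispersion used by the
  autocovariance descriptor is the *mean squared deviation* exactly as
  the normalization is printed in the source literature — it is a
  variance, not a standard deviation — with `sd = TRUE` exposing the
  square-rooted variant for comparison.
* **Profile input.** `readPssmProfile()` parses the `blastpgp -Q` text
  layout and defaults to the log-odds block (the common convention; the
  percentage block is selectable). Columns are reordered from the file
  header (NCBI order in real files) to the package alphabet. Running the
  profile search itself is out of scope; any N × 20 numeric matrix is
  accepted wherever a PSSM is.

## Numerical choices

* **Pseudo-PSSM standardization.** The printed row normalization of the
  pseudo-PSSM literature omits a square root and is therefore not a
  standard deviation; the default here is the z-score (square-rooted)
  form, with `strict = TRUE` reproducing the printed formula bit for
  bit. Zero-variance rows map to zero rows with a warning rather than
  erroring, because constant profile rows legitimately occur in short
  fixtures.
* **Average blocks with N not divisible by 20** uses block boundaries at
  `round(z N / 20)`, which guarantees 20 nonempty blocks for N ≥ 20.
* **Resizing.** The response matrix is resized to 250 × 250 only when
  larger, by align-corners bilinear interpolation — implemented in-package
  so that symmetric inputs stay symmetric to machine precision. The
  scalogram, when consumed as an image, is capped at 100 × 250 by the
  same rule for parity.
* **DCT.** "First 400 coefficients" is realized as the top-left 20 × 20
  low-frequency block of the orthonormal 2-D DCT-II (not zigzag order);
  inputs smaller than 20 × 20 are zero-padded.
* **Wavelets.** The Meyer continuous wavelet is defined in the frequency
  domain (so a constant signal transforms to exactly zero) over scales
  1..100; the discrete descriptor uses the biorthogonal 3.3 analysis
  bank with half-point symmetric padding, validated against an
  independent reference decomposition and frozen into the tests. The
  52-value budget of the discrete-wavelet descriptor is met as 4 levels
  × (5 DCT coefficients of the approximation + 4 approximation
  statistics + 4 detail statistics).
* **Split composition** follows the three-part textual description
  (N-terminal 20, middle, C-terminal 20 → 60 values); the conflicting
  printed size of 20 in the summary table is treated as a typo.
  Sequences shorter than 41 residues truncate the termini and encode an
  empty middle as zeros.
* **Global encoding** enumerates the 10 partitions of the six residue
  classes into two three-class subsets and takes four measures per
  characteristic sequence (frequency of 0s, of 1s, and of both
  transition directions) — 40 values. The printed dimension of 480
  implies a 12-fold segmentation structure that is not recoverable from
  the source text; rather than invent it, a `depth` parameter recomputes
  the measures on nested halves (40 · (2^depth − 1) values) and the
  default depth 1 reproduces the textual description.
* **AAIndexLoc grouping** clusters the 20 property values by k-means
  with 100 restarts under a fixed seed; groups are relabeled by
  ascending group minimum so the 25 dipeptide cells are deterministic.
* **Texture extraction** min-max scales any matrix to the [0, 255]
  intensity range (constant matrices map to mid-gray). LBP-HF uses
  (P = 16, R = 2) and (P = 8, R = 1) with bilinear neighbor
  interpolation; rotation invariance comes from DFT magnitudes along
  each orbit of rotated uniform patterns, giving (P − 1)(P/2 + 1) + 3
  features per parameterization (138 + 38 = 176). LPQ estimates local
  phase with Gaussian-windowed short-term Fourier filters at four low
  frequencies for window radii 3 and 5, sign-quantizes the 8
  real/imaginary parts into a byte, and histograms the codes
  (2 × 256 = 512); the decorrelation/whitening step is off by default
  for determinism (`whiten = TRUE`, correlation 0.9, enables it). The
  local variants split the image into three *horizontal* bands
  (sequence-position locality in N × 20 matrices); the split direction
  is not dictated by the source description and is documented here as a
  package choice.
* **Score commensurability.** A sum rule over heterogeneous SVMs needs a
  common score scale; the default converts each binary machine's output
  to a Platt class-posterior estimate, with `scoreType = "decision"`
  exposing raw margin values. Multiclass is one-versus-all throughout.
  Grid search covers cost 2^−5..2^15 and kernel width 2^−15..2^3 in
  powers of 4 by default, with ties broken toward the smallest cost and
  then the smallest width; `svmGrid()` makes the grid (and a
  1/dimension automatic width, `gamma = NA`) configurable because the
  full 110-point grid is rarely warranted at small sample sizes.
* **Evaluation.** AUC is the rank statistic with half-weight ties,
  oriented so that higher scores indicate the positive class (good
  classifiers score near 1); multiclass AUC is the unweighted mean of
  one-vs-rest areas. Cross-validation folds are stratified by class.
  Every protocol records an audit log of the row sets each training
  stage touched, and `auditLeakCount()` asserts train/test isolation.

## What the synthetic generators emulate — and what they do not

`twoClassDataset()` draws residues independently from class-conditional
composition weights (default: class A uniform on the first ten residues,
class B on the last ten — disjoint supports), lengths uniform on 60–100,
and builds a matched synthetic profile per record as 10 × one-hot(sequence)
plus integer noise in [−3, 3], clipped to the blastpgp log-odds range
[−10, 10]. This preserves the sequence-to-matrix coherence that
residue-grouping descriptors rely on, and gives every pipeline a signal
that a correct implementation must recover (cross-validated AUC ≥ 0.95
at 100 samples per class) and a null (no bias) that it must *not*
recover (AUC 0.5 ± 0.07). The generators deliberately do **not** emulate
real evolutionary profiles (no position-specific conservation structure,
no Dirichlet-mixture pseudocounts), residue autocorrelation along the
chain, or realistic backbone geometry beyond an ideal helix — so passing
these recovery checks demonstrates implementation correctness, not the
classification performance to expect on real data, which depends on
database-derived profiles this package intentionally does not compute.

Problem sizes used by the bundled checks (the package's own choice of
desk scale): 100 samples per class, 10-fold cross-validation, a 2 × 2
(or single-point, for the eight-component fusion with decision scores)
hyperparameter grid with 3 internal tuning folds, 200 random sequences
and 50 random matrices for the oracle-equivalence sweeps.

## Known limitations

* The 25-property ensembles are seed-parameterized random selections;
  the specific property subsets used in the source experiments are not
  published, so numerical results on real data are not expected to match
  a particular historical run.
* Only the first chain / first model of a PDB file contributes to the
  distance matrix; missing residues are simply absent.
* The LPQ local-frequency estimator is the Gaussian-windowed STFT; the
  Gaussian-derivative quadrature pair differs in filter shape but not in
  the quantization-and-histogram construction, and the blur-robustness
  property tested here holds for both.
* SVD descriptor lengths depend on the input shape; when used in a
  feature table they must be padded to a declared length (`padTo`).

## A worked example

```{r example, eval = FALSE}
ds <- twoClassDataset(nPerClass = 20, seed = 1)
feats <- t(vapply(ds$records,
                  function(r) featureValues(aacDescriptor(r)), numeric(20)))
res <- runProtocol(feats, ds$labels, protocol = "cv10", seed = 1,
                   grid = svmGrid(cost = c(1, 8), gamma = c(NA, 0.5)),
                   tuneFolds = 3)
res
auditLeakCount(res)
```

The composition classifier separates the disjoint-support classes
perfectly (accuracy and AUC 1.0 in every fold), and the audit log shows
zero training-stage touches of test rows.
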