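# protclass

Fixed-length protein descriptors and sum-rule SVM ensembles for
sequence-based protein classification.

Machine-learning predictors of protein attributes — subcellular
localization, DNA binding, fold class, virulence — need a fixed-length
numeric vector for a variable-length residue string. This package builds
the standard matrix representations of a protein and a catalogue of
descriptors on top of them, then couples each descriptor to a
support-vector machine and fuses the classifiers by a weighted sum rule.

## What it computes

**Representations.** For a protein *P* = (p₁, …, p_N) over the 20
canonical residues:

- **PSSM** — from a frequency-ratio profile *w*:
  PSSM(i, j) = Σₖ w(i, k) · Y(j, k), with *Y* a 20 × 20 substitution
  matrix (the classical Dayhoff/PAM250 matrix is bundled);
  `readPssmProfile()` parses `blastpgp -Q` output directly.
- **SMR** — row *i* is the substitution-matrix row of residue pᵢ.
- **PR** — PRM^d(i, j) = index(pᵢ, d) + index(p_j, d) for a
  physicochemical property *d* (AAindex scale), resized to 250 × 250 when
  larger.
- **WAVE** — Meyer continuous-wavelet scalogram (100 scales) of the
  property-encoded sequence.
- **DM** — Euclidean distance matrix of the Cα backbone.

**Descriptors** (declared dimension in parentheses): amino-acid
composition AS (20), 2-grams (400), quasi-residue couple QRC (1200),
autocovariance AC (40), AAIndexLoc AA (65), global encoding GE (40),
physicochemical 2-grams P2G (800), reduced-alphabet n-grams NG
(400/225/512/125/64), split composition SAC (60), discrete-wavelet DW
(52); and on any N × 20 profile: average blocks AB (400), single average
SA/SAN (400), matrix autocovariance AM (300), pseudo-PSSM PP (320), SVD,
DCT (400), soft profile n-grams BGR (400) / TGR (8000); plus image
textures LBP histogram Fourier LHF (176 global / 528 local) and local
phase quantization LPQ (512 global / 1536 local).

**Classification.** One RBF-kernel SVM (libsvm via e1071) per
descriptor; features normalized to [0, 1] using training rows only;
hyperparameters grid-searched on training rows only; one-versus-all
multiclass; weighted sum-rule fusion of per-class scores. The bundled
recipes are

    FUS1 = 2·AAS(AC) + 2·PSSM(SAN) + 4·PSSM(PP) + PSSM(LHF_G)
           + PSSM(BGR) + PSSM(TGR) + SMR(PP) + SMR(BGR)
    FUS2 = FUS1 + 2·DM(LPQ_G)

with evaluation by stratified 10-fold cross-validation or a declared
train/test split, reporting accuracy and one-versus-all AUC, and an
audit log proving test rows never leak into training stages.

## Worked example

```r
library(protclass)

# a seeded two-class dataset with disjoint composition supports
ds <- twoClassDataset(nPerClass = 20, seed = 1)
feats <- t(vapply(ds$records,
                  function(r) featureValues(aacDescriptor(r)), numeric(20)))
res <- runProtocol(feats, ds$labels, protocol = "cv10", seed = 1,
                   grid = svmGrid(cost = c(1, 8), gamma = c(NA, 0.5)),
                   tuneFolds = 3)
res
#> EvaluationResult [cv10]: accuracy 1.0000, AUC 1.0000 (10 folds)
auditLeakCount(res)
#> [1] 0
```

The two classes are drawn from disjoint residue supports, so a correct
composition pipeline must separate them perfectly — and does; the audit
count confirms no training stage touched a test row. Other pieces
compose the same way:

```r
p <- aaindexProperties()[[2]]      # an AAindex hydrophobicity-type scale
p
#> PhysicochemicalProperty ARGP820101 (mu = 0.9975, sigma = 0.6481)
pseudoPssm(randomProfileMatrix(60, seed = 2))
#> DescriptorVector PP  | dim 320
```

A thin command-line front end for descriptor extraction and
cross-validated evaluation lives in `inst/scripts/protclass-cli.R`.

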