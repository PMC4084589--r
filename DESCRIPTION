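Package: protclass
Title: Protein Representations, Fixed-Length Descriptors, and SVM
    Sum-Rule Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds matrix representations of proteins (profile-derived
    position-specific scoring matrices, substitution-matrix representation,
    physicochemical property response matrices, continuous-wavelet
    scalograms, C-alpha distance matrices) and a catalogue of fixed-length
    sequence, matrix, and texture descriptors: amino-acid composition and
    its split and reduced-alphabet variants, quasi-residue-couple and
    autocovariance pseudo-amino-acid features, physicochemical 2-grams,
    global encoding, discrete-wavelet statistics, average blocks, single
    average, pseudo-PSSM, matrix autocovariance, singular-value and
    discrete-cosine summaries, profile n-grams, and LBP-histogram-Fourier
    and local-phase-quantization textures. Classification couples each
    descriptor to a support vector machine with train-only [0,1]
    normalization and grid-search tuning, combined by weighted sum rule;
    cross-validated and hold-out evaluation protocols with accuracy and
    one-versus-all AUC are included, together with seeded synthetic-data
    generators for all input formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    Biostrings,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
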