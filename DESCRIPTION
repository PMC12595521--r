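Package: RcaDesign
Title: Machine-Learning-Directed Design of Thermotolerant Rubisco Activase Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an iterative machine-learning-directed engineering loop for
    thermotolerant Rubisco activase (Rca): curation of an ortholog multiple sequence
    alignment (identity and length filters, chloroplast transit peptide stripping,
    gap-fraction trimming), one-hot encoding over a 21-letter alphabet, a variational
    autoencoder on the alignment with an optional semi-supervised property head that
    predicts measured thermal tolerance, Hamming-constrained Gaussian sampling of the
    latent space to propose synthetic variants, and analysis of coupled ATPase assay
    screens (NADH A340 decay) into activity calls, per-sequence maximum retained
    heat-shock temperature, residual activity, and round tallies. A synthetic-data
    module plants a known genotype-to-thermotolerance map with a stability-activity
    trade-off so the whole loop is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
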