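Package: mitogradient
Title: Replication-Linked Mutational Gradients in Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies strand-asymmetric mutational gradients along circular
    mitochondrial genomes. Computes depth-normalized binned mutation
    frequencies from duplex-sequencing variant calls, fits robust (Huber
    M-estimator) gradient regressions within replication arcs including an
    age-by-position interaction model, runs composition-aware permutation
    tests for gradient significance and Monte-Carlo hot/cold-spot detection
    in the control region, measures population SNP-density gradients and
    cross-species genome-composition gradients, and ships a forward simulator
    of the asynchronous strand-displacement deamination model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
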