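Package: DIAdeconv
Title: Spectrum-Centric Deconvolution of Data-Independent Acquisition
    Proteomics Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Library-free deconvolution of SWATH-style data-independent
    acquisition (DIA) runs into pseudo-tandem mass spectra. Fragment
    extracted-ion chromatograms inside fixed-width retention-time sliders
    are embedded with a triplet-loss variational autoencoder, grouped by
    k-means, assigned to candidate precursors through an inverted-index
    peptide query with hyperscore ranking, gated by a convolutional
    co-elution classifier, mass-recalibrated against internal calibrants,
    and written as MGF for downstream database searching. Includes a
    synthetic SWATH run generator with full ground truth for training and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    mzR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
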