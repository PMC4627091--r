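Package: aptascan
Title: Binding and Stability Landscapes from Fluorogenic Aptamer Scanning
    Mutagenesis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs thermodynamic binding (free energy, enthalpy) and
    stability (apparent melting temperature) landscapes of fluorogenic RNA
    aptamers such as Spinach from saturation scanning-mutagenesis
    fluorescence data acquired on microfluidic chips. Provides mutant-library
    enumeration (single-point, compensatory double-point and deletion
    variants) with two-fragment assembly design and chip-layout planning,
    pull-down spot segmentation with background-corrected RNA-normalised
    signal extraction, two-state binding-isotherm and melting-curve fitting
    with Van't Hoff enthalpy regression, per-position composite landscape
    scoring with replicate error propagation, quantile-based selection of
    engineering candidates, compensatory double-mutant rescue analysis, and a
    seeded synthetic chip-data generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: Software, SequenceMatching, Regression, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
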