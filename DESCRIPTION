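Package: domchar
Title: Molecular Characterization of Dissolved Organic Matter and Its
    Bioactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing dissolved organic matter (DOM) at the
    molecular-formula level from ultrahigh-resolution negative-mode mass
    spectra and for relating molecular composition to bioassay activity.
    Implements noise filtering by a method-detection-limit threshold, spectral
    recalibration, ppm-tolerance mass alignment across replicate measurements,
    exhaustive CHNOSP molecular-formula attribution with heteroatom and
    isotope plausibility screens and homologous-series support, van Krevelen
    style compound-class assignment via the modified aromaticity index and
    double-bond equivalents, intensity-weighted sample descriptors and
    exclusivity statistics, principal coordinate analysis on Bray-Curtis
    dissimilarities with permutation-based descriptor fitting, and bioactivity
    quantification (percent inhibition, IC50 by log-linear interpolation or
    four-parameter logistic fit, Trolox-equivalent antioxidant capacity,
    descriptor-activity regressions). A synthetic-data generator emulates
    source-dependent DOM composition and linked bioassay responses so that
    every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
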