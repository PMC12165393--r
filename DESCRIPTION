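Package: gridtorus
Title: Degree of Toroidality of Grid-Cell Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how close the activity manifold of a neural
    population is to a torus. Persistence barcodes computed with built-in
    Vietoris-Rips persistent cohomology are compared to an idealized toroidal
    reference barcode through a normalized bottleneck distance, yielding a
    continuous degree of toroidality (Gamma1, Gamma2). The package also
    provides a rate-modulated Poisson simulator of grid-cell modules with
    hexagonal (or square) field lattices and an oscillator bank for temporal
    modulation, a synthetic open-field foraging trajectory generator, the
    spike-train to barcode preprocessing pipeline (Gaussian smoothing,
    binning, population-vector selection, PCA, density-aware downsampling),
    spike-time jittering with sigmoid critical-timescale estimation, ratemaps
    and grid scores, and spike-train spectral analysis with eta/theta band
    powers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    FNN,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
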