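Package: lfdat
Title: Longitudinal Functional Data Association Testing for Gene Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based association testing between a dense set of SNPs
    (treated as a function of genomic position) and a longitudinal
    quantitative trait (treated as a function of time), via a penalized
    function-on-function regression with a tensor-product B-spline
    coefficient surface and two-directional roughness penalties.  Provides
    per-time-point F tests for the null hypothesis of no genetic effect,
    a single-time-point smoothed functional linear model comparator,
    integrated squared error and prediction error metrics, and a full
    simulation framework (linkage-equilibrium and linkage-disequilibrium
    genotype generators, MAF-dependent effect sizes, gene-switching time
    effects) for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    vcfR,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
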