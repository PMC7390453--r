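Package: landgen
Title: Landscape Population Genomics of Invasive Aedes Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for population- and landscape-genomic
    analysis of multi-population SNP data, built around the study design used
    for Indo-Pacific Aedes aegypti and Ae. albopictus: depth- and
    missingness-based SNP filtering, KING-robust kinship estimation with
    first-order kin pruning, balanced subsampling with confidence intervals,
    Hedrick standardised pairwise F'ST, per-population diversity statistics
    and folded allele frequency spectra, DAPC-style cluster-number selection
    by BIC/AIC, and distance-based redundancy analysis (dbRDA) on PCNM
    spatial eigenvectors with Freedman-Lane permutation tests of
    isolation-by-distance and transport-connectivity hypotheses. Includes a
    seedable synthetic-data generator producing multi-population diploid SNP
    matrices with connectivity-modulated isolation by distance, drift
    signatures, missing calls, read depths and planted kin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    geosphere,
    vcfR,
    jsonlite,
    yaml,
    withr
Suggests:
    vegan,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
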