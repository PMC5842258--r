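Package: lodgeAT
Title: Associative Transcriptomics and Stem Biomechanics for Lodging Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting stem lodging resistance in Brassica napus
    and related crops. Derives absolute and material stem-strength traits
    (Fmax, F/V, second moment of area, modulus of rupture, modulus of
    elasticity) from three-point bend-test force-displacement curves and
    stem cross-section geometry; runs structure- and kinship-corrected
    mixed-linear-model SNP association scans and gene expression marker
    (GEM) scans on transcriptome-derived markers; maps associated GEMs'
    transcript abundance back onto SNPs as a secondary trait; validates
    candidate markers by allele-class t-tests on independent panels; and
    compares FTIR cell-wall spectra between genotype groups. A synthetic
    diversity-panel simulator with known ground truth (admixed
    subpopulations, cis-eQTL expression, planted SNP and
    expression-mediated trait effects, piecewise-elastic bend curves,
    two-peak esterification spectra) makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    MASS,
    pracma,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
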