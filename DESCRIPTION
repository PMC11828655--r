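Package: lattivar
Title: Variability, Trait Association and Diversity Analysis for Simple
    Lattice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biometrical analysis of germplasm evaluation trials laid out as
    simple (square) lattice designs: intra-block analysis of variance with
    block-adjusted accession means and Tukey mean separation, genotypic and
    phenotypic variance components with coefficients of variation,
    broad-sense heritability and genetic advance under selection, genotypic
    and phenotypic correlation matrices estimated from variance and
    covariance components, path-coefficient partitioning of trait
    correlations with grain yield into direct and indirect effects,
    Euclidean-distance and UPGMA clustering of accessions on standardized
    traits, and principal component analysis of the trait correlation
    matrix. Includes a seeded multivariate simulator of lattice trials for
    parameter-recovery studies and an end-to-end pipeline that writes the
    full report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
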