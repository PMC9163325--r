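Package: rhizobsa
Title: Bulked-Segregant QTL Detection for Rhizosheath Size with the
    Euclidean-Distance Statistic
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) for rhizosheath
    size (root-adhering soil mass per unit root mass, RAS/RT) by bulked
    segregant analysis of pooled sequencing data from an F2 population.
    Implements phenotype modelling (log-ratio block ANOVA, residual-based
    selection of 10 percent tail bulks, broad-sense heritability from
    variance components, trait correlation matrices, mycorrhizal
    colonization scores), the SNP quality filter cascade for two-bulk
    allele-depth tables, the per-marker Euclidean-distance statistic with
    its fourth-power 100-marker window form and a simulation-based
    genome-wide significance threshold, significant-region calling and
    intersection with GWAS windows, and a seeded generator of synthetic F2
    genotypes, phenotypes and pooled read counts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    graphics,
    grDevices,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
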