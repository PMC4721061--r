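Package: famews
Title: Family-Based Genome- and Epigenome-Wide Association Analysis of the
    Hypertriglyceridemic-Waist Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variance-component polygenic models for extended pedigrees
    (continuous and liability-threshold traits), bivariate decomposition of
    phenotypic correlation into genetic and environmental components,
    epigenome- and genome-wide association scans with probe and SNP quality
    filters, genomic-inflation and Benjamini-Hochberg false-discovery-rate
    correction, liability-scale odds ratios, Sobel mediation,
    Kullback-Leibler R-squared model comparison, and Bland-Altman agreement
    statistics.  Includes a synthetic-data generator (pedigrees, polygenic
    traits, methylation beta matrices, Mendelian genotypes) so that the full
    pipeline can be exercised and calibrated without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
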