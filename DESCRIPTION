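Package: metanova
Title: ANOVA-Based Multivariate Analysis of Designed Metabolomics Experiments
Version: 0.1.0
Authors@R:
    person("metanova", "developers", email = "metanova@example.org",
           role = c("aut", "cre"))
Description: Statistical assessment of experimental design factors in
    designed metabolomics (LC-MS feature matrices and total-ion-current
    chromatograms) by three multivariate ANOVA-based methods: ANOVA
    simultaneous component analysis (ASCA), regularized MANOVA with
    Ledoit-Wolf shrinkage of the within-group covariance, and group-wise
    ASCA with sparse group-restricted loadings.  Factor significance is
    tested by sum-of-squares permutation tests.  Includes PLS-DA with VIP
    scores and selectivity ratio, univariate testing with
    Benjamini-Hochberg correction, top-k variable-selection concordance
    analysis (Venn partitions, profile correlations, coincidence counts),
    a simplified region-of-interest feature extractor for centroided scan
    tables, internal-standard normalization, and a synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
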