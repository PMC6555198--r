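Package: transtat
Title: Biostatistical Exploration of Gene-Expression Matrices
Version: 0.1.0
Authors@R: person("transtat", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scriptable toolbox for exploratory biostatistics on bulk and
    single-cell RNA-Seq expression matrices: low-expression filtering and five
    normalization schemes (FPKM, RPKM, TPM, upper quartile, control-gene RUV)
    with relative log expression (RLE) quality-control profiles; maximum
    likelihood fitting of six heavy-tailed expression distributions ranked by
    AIC, with a power-law low-expression cutoff report; Pearson and Spearman
    sample correlation matrices and pairwise scatter tables; PCA with variance
    decomposition and seeded k-means; Shannon entropy under Doane binning and
    the squared coefficient of variation noise matrix over sample pairs; Ward
    hierarchical clustering of z-scored expression with per-cluster gene lists
    and volcano-plot categorization of differential-expression tables.
    Includes a deterministic synthetic-data generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
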