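Package: countnorm
Title: Global Normalization Factors for Gene Expression Count Matrices
Version: 1.0.0
Authors@R:
    person("Countnorm", "Developers", email = "countnorm@example.org",
           role = c("aut", "cre"))
Description: Computes global (per-sample) normalization factors for bulk and
    single-cell gene-expression count matrices by library-size methods (TN,
    TC, CR, NR), control-set methods (HG7 housekeeping genes, ERCC spike-ins,
    GAPDH), average-bulk methods modified to ignore zeros (DESeq
    median-of-ratios, RLE, upper-quartile, TMM), and the Total Ubiquitous
    (TU) method whose trimming parameters are chosen by maximizing the area
    under the normalized coefficient-of-variation threshold curve (AUCVC).
    Provides evaluation metrics (AUCVC, median Spearman correlation of
    ubiquitous gene pairs, RLE_MED, RLE_IQR), method ranking under the
    consistency-of-metrics principle, factor clustering by rank-correlation
    distance, and a negative-binomial simulator with known ground-truth
    depth factors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    ape,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
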