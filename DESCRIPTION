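Package: countbench
Title: Normalization, Filtering and Differential-Expression Benchmarking for
    Multi-Factor RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a complete analysis framework for multi-factor RNA-Seq
    read-count studies of individual organisms: seven count-normalization
    methods (total-count, upper-quartile, median, TMM, median-of-ratios size
    factors, full quantile, RPKM) plus a minimal RUVg factor construction;
    empirical low-expression thresholding from intergenic background reads
    with three filtering workflows; sample-identity quality control from SNP
    base calls and sex-dimorphic expression; negative-binomial GLM and
    ln-ANOVA differential-expression engines with a nested model-testing
    ladder and Benjamini-Hochberg FDR control; closed-form factorial
    noncentral-F power analysis and an empirical subsampling power procedure;
    and agreement metrics for comparing analysis choices. A synthetic-data
    generator emulates the structure of a large factorial single-fly
    expression study (genotype x environment x sex with replicates, ERCC
    spike-in controls, intergenic background reads, duplicate libraries and
    informative SNP sites) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    DESeq2,
    edgeR,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
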