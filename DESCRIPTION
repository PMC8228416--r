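Package: rrbsdm
Title: Differential DNA Methylation Analysis for RRBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-CpG differential methylation testing for reduced representation
    bisulfite sequencing (RRBS) count data, using an overdispersion-corrected
    logistic-model chi-square test with Benjamini-Hochberg multiple-testing
    correction. Includes reading and writing of Bismark coverage files, assembly
    of cross-sample methylation count matrices, genomic-context annotation of
    CpGs (promoter/exon/intron/intergenic and CpG island/shore/open sea),
    spatial clustering analysis of differentially methylated sites against a
    resampling null, same-direction co-methylation summaries, 1-Mb bin density
    differencing between comparisons, nested correlation analysis, an absolute
    methylation-difference screen, and a beta-binomial RRBS simulator with
    known injected group effects for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
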