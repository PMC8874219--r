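Package: mrsd
Title: Minimum Required Sequencing Depth for Splice-Junction Coverage in RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, per transcript and tissue, the minimum required
    sequencing depth (MRSD): the number of millions of uniquely mapping
    RNA-seq reads needed for a chosen proportion of a transcript's splice
    junctions to each reach a chosen read coverage, holding for a chosen
    proportion of control samples. Builds reference sets from per-sample
    splice-junction counts (STAR SJ.out.tab or generic TSV), selects one
    junction-set transcript model per gene via a MANE / RefSeq-composite /
    annotation-union hierarchy, scores and ranks aberrant splice events in
    case samples against the reference cohort using normalized read counts,
    and provides evaluation tools: predictive-value assessment on held-out
    samples, binomial read downsampling, bootstrap background estimation,
    expression (TPM) comparison, gene-panel tissue recommendation, and
    feasibility annotation of putative splice-impacting variants. A
    negative-binomial synthetic-data generator with known ground truth
    supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
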