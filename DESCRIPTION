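Package: rbcfdna
Title: Somatic RB1 Mutation Detection in Plasma Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-informed genotyping and de novo calling of low variant
    allele frequency somatic RB1 mutations in plasma cell-free DNA from
    retinoblastoma patients. Detection decisions are made against an
    empirical per-variant background null built from a panel of unmatched
    buffy-coat samples (mean VAF plus k standard deviations), with a
    matched buffy coat used to separate germline from somatic variants.
    Includes a count-level synthetic cohort generator that emulates a
    ten-patient targeted-panel study (sequencing error, artifact-flagged
    reads, germline heterozygotes, technical replicates) together with
    ground truth for scoring sensitivity, specificity, VAF recovery and
    replicate concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
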