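Package: nadtseq
Title: Activity-Dependent Transcription Analysis of Pol II and TDRD3 ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies RNA polymerase II and TDRD3 ChIP-seq occupancy at
    promoter (TSS) windows and exon unions with fractional multimapper
    weighting and PCR-duplicate capping, normalizes replicate signals to an
    untreated wild-type baseline, and fits gene-wise genotype-by-treatment
    two-way ANOVA models with pooled-MSE pairwise contrasts, FDR control and
    fold-change response classification.  Includes SICER-style broad
    binding-island calling, parametric gene-set enrichment (PAGE) on log2
    signal ratios, metagene TSS profiles, gene-panel summaries, and a
    synthetic-study generator with known ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
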