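Package: TBPscan
Title: TBP-Promoter Binding Affinity Changes at Regulatory SNPs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the affinity (-ln KD) of TATA-binding protein (TBP)
    for 90-bp proximal core-promoter alleles with a three-mechanism
    window-maximum scoring model (sliding along DNA, position-weight-matrix
    site recognition, and DNA bending), compares ancestral and minor alleles
    of promoter SNPs with a Z statistic and a coarse significance ladder,
    classifies the predicted expression change (up, down, or none), ships a
    curated machine-readable table of published TATA-box SNP markers with
    consistency checks, and provides rank-concordance statistics
    (Pearson, Spearman, Kendall, Goodman-Kruskal gamma) for comparing
    predicted with measured affinities. A synthetic-data generator produces
    promoters, injected variants, and noisy pseudo-EMSA measurements so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SNP, Transcription, GeneRegulation, SequenceMatching, Software
RoxygenNote: 7.3.3
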