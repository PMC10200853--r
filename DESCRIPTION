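Package: mtSomatic
Title: Somatic Mitochondrial DNA Variant Filtering and Copy-Number Estimation for Tumour/Normal Pairs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-sample mitochondrial DNA copy number from the
    chrM/autosome sequencing depth ratio with tumour purity and ploidy
    correction, and calls somatic mitochondrial heteroplasmies from paired
    tumour/normal chrM variant call sets. Variant calls from two independent
    callers are union-merged and passed through a multi-criteria filter stack
    (position blacklist, read support, base quality, strand balance, read
    position, read-length/mapping-quality/edit-distance differentials, read
    context), germline polymorphism removal, and a panel-of-normals VAF noise
    floor; passing variants are classified as somatic or tumour-specific
    dysplastic from the matched-normal allele fraction, annotated against the
    mitochondrial gene model, and summarized per group with Welch t-tests.
    A seeded synthetic-cohort generator emits paired tumour/normal call sets
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SomaticMutation, VariantAnnotation, CopyNumberVariation, Sequencing
RoxygenNote: 7.3.3
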