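Package: tnsomatic
Title: Tumour-Normal Subtraction Analysis of Somatic Variants from Long-Read
    and Short-Read Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Subtraction-based somatic variant analysis for matched
    tumour/normal genome sequencing. Implements filtered somatic SNV calling
    from annotated small-variant call sets (initial quality filter, germline
    subtraction on CHROM/POS/ALT, strand-bias exclusion, final count/quality
    filter), somatic structural-variant derivation by germline subtraction
    with length-scaled breakpoint tolerance plus cross-method matching and
    FNR/FDR benchmarking, a windowed copy-number pipeline (normalised log2
    ratios with coverage masking, circular binary segmentation, ploidy-2
    recentring, tumour purity estimation from segment-mean clusters, and
    integer ploidy classification against theoretical segment means), a
    closed-form cis/trans expected-VAF model for a somatic SNV co-located
    with a heterogeneous deletion, read haplotagging by majority vote over
    phased heterozygous sites, and seeded synthetic-data generators for
    every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
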