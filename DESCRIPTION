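Package: lncsel
Title: Conservation and Selection Analysis for Long Non-Coding RNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests for purifying selection and phylogenetic conservation at
    long non-coding RNA loci such as the HERV-H-derived primate lncRNA ESRG.
    Reads population single-nucleotide variants (VCF with allele counts) and
    per-site coverage summaries, stratifies sites into exon, intron and
    LTR-derived classes, builds downsampled site-frequency spectra by
    hypergeometric projection, contrasts singleton fractions against a
    synonymous-site neutral reference (chi-squared), contrasts human-lineage
    substitutions inferred from a human-chimpanzee-bonobo alignment against
    polymorphism in McDonald-Kreitman-style Fisher tests, summarizes base-wise
    conservation scores over exons, and screens cross-species expression with
    a negative-binomial interaction model. A Poisson-random-field synthetic
    data generator with known selection coefficients makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    DESeq2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
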