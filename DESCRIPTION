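Package: mitolineage
Title: Maternal-Lineage Tracing, Mitogenome Variant Classification and
    Resampling-Based Breeding-Value Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing maternal (dam-line) lineages through livestock
    pedigrees, classifying mitochondrial genome sites as homoplasmic or
    heteroplasmic from per-site base counts, annotating coding consequences
    under the vertebrate mitochondrial genetic code, mapping positions
    between mitogenomes by global alignment, predicting PCR amplicons in
    silico, and comparing trait breeding values of a carrier group against a
    resampled null distribution with equal-tailed credibility intervals.
    Includes a synthetic-data module that generates pedigrees with strict
    maternal haplotype transmission, pileups with binomial sequencing noise,
    and Gaussian breeding-value tables, so that every pipeline stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
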