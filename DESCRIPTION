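Package: vcfcompare
Title: Comparison, Filtering, Grouping and Benchmarking of VCF Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for the set-wise comparison of variant call format
    (VCF) files. Variants are identified by exact match on chromosome,
    position, reference and alternate allele. Call sets can be filtered by
    FILTER status, genomic regions (BED, via a single-pass sorted sweep),
    variant type and chromosome; grouped by file metadata with union,
    intersection or majority pooling; compared with multi-set Venn tallies
    and pairwise Jaccard similarity with hierarchical clustering; and
    benchmarked against a golden set by precision and recall. Results are
    written as CSV tables, PNG figures and compressed VCF files, and a
    command-line front end exposes the whole pipeline. A synthetic-data
    generator produces small VCF/BED/CSV inputs with controlled overlap
    structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    pheatmap,
    stats,
    tools,
    utils,
    grDevices,
    vcfR,
    withr
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
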