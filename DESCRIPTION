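Package: clonefate
Title: Clone Barcode Capture and Clonal Fate Statistics for Lentiviral
    Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lentiviral clone-barcode lineage tracing in
    single-cell RNA-seq experiments. Extracts random 20-base clone tags
    from paired-end reads using fixed flanking anchor sequences with
    mismatch tolerance, collapses unique molecular identifiers (UMIs)
    by one-mismatch correction, resolves cells carrying multiple clone
    barcodes, and applies per-cell quality filters. From the resulting
    clone-by-lineage fate table it computes clone-level fate statistics
    for hematopoietic stem and progenitor cell (HSPC) clones: the output
    value (ratio of a clone's downstream share to its HSPC share), the
    M-value potency class (number of downstream lineages seeded), and
    per-lineage differentiation-bias scores, plus lymphoid/myeloid bias
    calls and transduction summaries. A clone simulator with known
    output regimes, potency, Dirichlet lineage bias, dropout and
    sequencing error generates ground-truth datasets and FASTQ reads so
    every stage of the pipeline can be verified by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
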