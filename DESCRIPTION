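Package: cassex
Title: Cassette-Exon Alternative Splicing Analysis from Splice-Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De-novo discovery of cassette-exon skipping events from
    splice-junction read counts (STAR SJ.out.tab dialect), percent-spliced-in
    (PSI) quantification, paired tumor/normal differential splicing calling,
    cross-cancer recurrence and coherence classification, splicing-marker
    detection, direction-stratified k-mer motif enrichment in flanking
    introns, and conservation profiling around motif occurrences. Includes a
    fully self-contained synthetic-cohort generator with planted ground truth
    so every stage of the pipeline can be exercised and validated without
    access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
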