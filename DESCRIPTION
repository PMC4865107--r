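Package: topomap
Title: Genome-Wide Mapping of Bacterial Topoisomerase IV Binding and Cleavage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide binding (ChIP-seq) and
    quinolone-trapped cleavage (NorflIP) of topoisomerase IV on circular
    bacterial chromosomes. Provides coverage-track processing (circular
    smoothing, library-size and GC normalization, artifact masking),
    template-correlation peak callers for symmetric binding peaks and for
    the strand-asymmetric cleavage signature, cleavage-point and peak-shape
    estimators, marker-frequency analysis of synchronized replication with
    segmented breakpoint fitting, a replication-coupled "comet" occupancy
    null model, genomic-context statistics (gene localization, proximity to
    highly expressed transcription units, interval-overlap enrichment,
    dinucleotide and GATC-spacing profiles), and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
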