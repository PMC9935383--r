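Package: strandquant
Title: Strand-Aware Per-Nucleotide Coverage of Viral Vector Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sense and antisense transcription per nucleotide
    position on viral vector construct references from stranded paired-end
    RNA-seq alignments. Strand is assigned from the first-mate alignment
    orientation under a configurable library convention, counts are
    normalised by aligned reads and integrated across sample groups with
    min/mean/max envelopes, and region-level metrics (retention ratio
    across a termination anchor, antisense fraction) operationalise
    read drop-off and antisense transcription on lentiviral transfer
    vectors. Includes a stranded paired-end read simulator with exact
    ground truth for end-to-end validation, and calculators for
    lentiviral titres (TU/mL, GP/mL), qPCR copies per cell, and
    mass/molar construct transfection ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
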