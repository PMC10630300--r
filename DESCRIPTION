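Package: regenscreen
Title: Deconvolution and Hit Calling for Pooled In Vivo shRNA Regeneration Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled shRNA screens read out by amplicon
    deep sequencing, modeled on chimeric-liver damage-regeneration selection
    experiments. Demultiplexes reads by sample barcode, counts exact matches
    to a guide library, converts counts to relative abundances and log2 fold
    changes against the starting plasmid pool, aggregates biological
    replicates with a sign-consistency score, and calls gene-level hits under
    a two-fold / at-least-two-independent-shRNAs rule with control-based QC.
    Ships a clonal-competition simulator (damage-regeneration cycles with
    per-shRNA fitness) that generates FASTQ, counts and ground truth for
    end-to-end testing, and a cross-species differential-expression overlap
    procedure (count prefilter, significance and fold-change filtering,
    ortholog mapping, concordant up/down partition) with a matched synthetic
    DE-table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
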