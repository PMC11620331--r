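Package: forkcollapse
Title: Quantification of Replication-Coupled DNA Double-Strand Breaks from
    Strand-Specific Break-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify DNA double-strand breaks (DSBs) arising from
    replication fork collisions with single-strand nicks, using strand-specific
    break-end coverage (END-seq-style data). Provides spike-in normalization,
    threshold-based peak calling with the standard qualification rules, the
    peak-asymmetry statistic separating single-ended from double-ended DSBs,
    resection-tract length estimation (boundary and sliding-window methods),
    replication-fork-directionality (RFD) computation and leading/lagging nick
    classification, and deletion/microhomology calling from amplicon reads.
    Includes a synthetic-data generator that simulates nick-induced fork
    collapse under a configurable collision model so every analysis stage can
    be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
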