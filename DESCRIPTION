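Package: forktrace
Title: Single-Molecule Replication Fork Mapping from Nanopore BrdU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects 5-bromo-2'-deoxyuridine (BrdU) incorporation along
    individual nanopore sequencing reads from reference-aligned current
    shifts, using both a transition-matrix caller and a small
    one-dimensional convolutional estimator.  Oriented BrdU tracks from
    pulse-chase labeling experiments are segmented, scored and turned into
    per-molecule replication initiation and termination events, which are
    assembled into genome-wide replication fork directionality (RFD),
    origin efficiency metric (OEM) and event-density profiles, clustered
    against annotation tracks, and compared with randomized controls.  A
    seeded pulse-chase signal simulator generates transition matrices,
    resquiggled reads, chimeric reads and whole-genome read populations so
    that every stage of the pipeline can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
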