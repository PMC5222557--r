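Package: okseqr
Title: Okazaki-Fragment Based Mapping of DNA Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps DNA replication origins from strand-specific Okazaki
    fragment sequencing (OK-seq). Stranded fragment alignments are binned,
    median-smoothed and normalized into a replication fork directionality
    profile; origins are called as peaks of a two-window Watson-fraction
    transition metric and annotated with firing efficiency and
    initiation-zone (transition zone) width. Downstream analyses quantify
    the association of chromatin marks (ChIP peaks and signal) with origins,
    gene orientation bias and positional gene-set enrichment around origins,
    and the coupling of an embryonic expression time course to origin
    proximity. A stochastic replication simulator (per-cell origin firing,
    bidirectional forks, nucleosome-periodic Okazaki fragment lengths)
    provides ground truth for parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
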