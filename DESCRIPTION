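Package: puseqr
Title: Polymerase Usage Sequencing (Pu-Seq) Analysis and Replication-Program Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of polymerase usage sequencing (Pu-Seq) data: per-bin
    polymerase tracks from strand-specific ribonucleotide (rNMP) counts,
    differential-based calling of replication origins with firing-efficiency
    estimation, selection of efficient origins and replication termination
    zones, and origin-centred / rescaled termination-zone meta-profiles.
    Includes a stochastic simulator of the chromosomal replication program
    (origin firing, fork progression, passive replication) that generates
    realistic strand-specific count tables with known ground truth, and small
    utilities for RT-qPCR relative transcript levels and culture doubling
    times.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
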