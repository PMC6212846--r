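Package: repliddpcr
Title: Locus-Specific DNA Replication Timing from Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures locus-specific DNA replication timing from droplet
    digital PCR (ddPCR) droplet counts or from binned sort-seq read counts.
    Converts positive-droplet fractions to absolute template concentrations
    by Poisson correction with analytic and replicate-based uncertainty,
    normalizes per-probe concentrations to relative copy number on the
    one-to-two replication scale, fits Boltzmann sigmoid kinetics to
    synchronized time courses to estimate median replication time (Trep),
    computes dynamic-range-invariant replication indices for mutant
    screening, derives probe-level resolution by one-way ANOVA with Tukey
    HSD, and processes binned replicating/non-replicating count ratios with
    a unit-range adjustment. A synthetic-data generator simulates
    replication-timing landscapes, cell populations (synchronized, sorted,
    asynchronous), Poisson droplet partitioning and overdispersed
    sequencing counts so the full pipeline is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
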