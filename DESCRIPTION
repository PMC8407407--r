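Package: rpodprofiler
Title: Species-Level Pseudomonas Profiling from rpoD Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for species-level profiling of Pseudomonas communities
    with the rpoD marker gene. Provides in-silico PCR with degenerate IUPAC
    primers (bounded mismatch and indel budgets), construction of
    primer-trimmed, taxonomy-labelled amplicon reference databases,
    classification of non-overlapping paired-end amplicon reads by concordant
    banded local alignment with a best-versus-second-best uniqueness score,
    mock-community benchmarking statistics, community ecology analyses
    (Bray-Curtis, PCoA, NMDS, beta dispersion, Chao1, rarefaction), a
    qPCR-anchored absolute abundance calculator, and a seeded synthetic-data
    generator for reference databases, primer-bearing templates and
    error-bearing paired reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
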