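Package: riboevo
Title: Fidelity, Population Dynamics, Structure and Kinetics of an Evolving
    RNA Polymerase Ribozyme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for deep-sequencing and biochemical data from
    directed evolution of an RNA polymerase ribozyme. Aligns
    ribozyme-synthesized product reads to a reference template and tallies
    matches, mismatches, insertions and deletions per template position to
    estimate copying fidelity and the mutation spectrum; clusters the
    P7/P8 region of population amplicons at 100% identity with terminal
    slack and tracks cluster frequencies across rounds of evolution;
    encodes competing secondary-structure models (old P7 stem-loop versus
    the evolved P7+P8 pseudoknot), scores compensatory-mutation support for
    stem pairs, and normalizes in-line probing intensities onto structures;
    fits burst-phase exponential and linear initial-rate kinetic models.
    A synthetic-data generator with known ground truth drives every stage
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
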