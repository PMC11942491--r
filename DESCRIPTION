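Package: strcaller
Title: Tandem Repeat Genotyping, Motif Decomposition and Clinical
    Classification from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing short tandem repeat (STR) expansions
    from long sequencing reads: a curated catalog of disease-associated
    repeat loci with clinical repeat-count ranges, exact dynamic-programming
    decomposition of repeat regions into motif runs and interruptions,
    flank-anchored allele calling with somatic mosaicism ranges and
    lower bounds from non-spanning reads, per-locus clinical classification
    under dominant, recessive and X-linked logic, CpG methylation summaries
    and their association with repeat interruptions, a two-tier short-read /
    long-read triage rule, read simulators for validation, and cohort-level
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
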