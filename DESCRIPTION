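Package: sirnadesign
Title: Multi-Filter Design of Small Interfering RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design of 19-nt small interfering RNAs against a gene's full
    transcript set. Candidate target sites are enumerated in regions conserved
    across transcript isoforms and free of known single-nucleotide
    polymorphisms, scored with an ensemble of rule-based and linear efficacy
    models gated by thresholds derived as mean +/- 2 SD from high-efficacy
    training scores, gated by target-site accessibility computed from a
    Boltzmann-weighted base-pairing partition function, and screened against a
    background transcriptome for complete, near-complete (18/19) and
    seed-matched (guide positions 2-7 vs 3' UTRs) off-targets. Accepted
    duplexes are ranked and written in a FASTA-like annotated format with a
    TSV sidecar. Includes a seed-deterministic synthetic-data generator for
    fixture construction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
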