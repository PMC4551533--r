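Package: selexenrich
Title: Enrichment Analysis and Binding Models for CE-SELEX High-Throughput Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for aptamer selections (SELEX) characterized by
    high-throughput sequencing. Converts per-round FASTQ pools into
    deduplicated random-region count tables (primer trimming with a mismatch
    budget and no indels, length filtering, duplication statistics), computes
    per-sequence fold enrichment across selection rounds, clusters enriched
    sequences by global alignment identity with a greedy incremental rule,
    and applies negative-pool and library-homolog filters to produce ranked
    candidate-aptamer tables. Also implements quadratic ligand-depletion
    binding isotherms for affinity probe capillary electrophoresis and
    fluorescence anisotropy titrations, with nonlinear least-squares Kd
    estimation, plus a synthetic multi-round CE-SELEX simulator with planted
    motif affinities, parasitic sequences, and adaptor contamination for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
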