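reported_tsv <- function(name) {
  path <- system.file("extdata", name, package = "selexenrich",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reported values of the HE4 CE-SELEX study
#'
#' Small reference tables transcribed from the published HE4 aptamer
#' selection: per-round Illumina read counts and sequence-duplication
#' percentages (`selex_reported_rounds`), the five candidate aptamers
#' chosen for in vitro testing with their round, enrichment rank, fold
#' enrichment, sequence, external binding-potential Z-score and cluster
#' size (`selex_reported_candidates`), and the dissociation constants
#' measured for those candidates by fluorescence anisotropy and affinity
#' probe CE (`selex_reported_kd`; `anisotropy_censored` marks a
#' lower-bound measurement). These are inputs for desk-scale checks and
#' for parameterizing simulations, not outputs of this package.
#'
#' @return A data.frame (see Details above for columns).
#' @examples
#' mean(selex_reported_rounds()$reads_millions)  # 6.4
#' nchar(selex_reported_candidates()$sequence)
#' @export
selex_reported_rounds <- function() {
  reported_tsv("reported_sequencing_rounds.tsv")
}

#' @rdname selex_reported_rounds
#' @export
selex_reported_candidates <- function() {
  reported_tsv("reported_candidates.tsv")
}

#' @rdname selex_reported_rounds
#' @export
selex_reported_kd <- function() {
  reported_tsv("reported_kd.tsv")
}
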