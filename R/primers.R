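#' Selection primers of the HE4 CE-SELEX library
#'
#' Fixed flanking sequences of the selection library: the forward primer and
#' the reverse-primer binding region, both written in the orientation in
#' which they appear in a sequencing read (forward primer, 25-nt random
#' region, reverse-primer region, then any downstream adaptor). The reverse
#' PCR primer itself is the reverse complement of the `rev` element.
#'
#' @return Named character vector with elements `fwd` and `rev`, each 20 nt.
#' @examples
#' he4_primers()
#' @export
he4_primers <- function() {
  c(fwd = "AGCAGCACAGAGGTCAGATG",
    rev = "CCTATGCGTGCTACCGTGAA")
}
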