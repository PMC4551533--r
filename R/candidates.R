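#' Negative-pool membership of a sequence
#'
#' A candidate that shows up in the pools sequenced from counter-selection
#' (negative) rounds is suspected of binding the purification tag or of
#' being amplification-parasitic rather than target-selected.
#'
#' @param seq Random-region sequence.
#' @param negative_pools List of [round_pool()]s with polarity `"negative"`.
#' @param min_count Minimum count that counts as presence (default 1, the
#'   strict "not found in any negative round" reading).
#' @return `TRUE` iff `seq` occurs with count `>= min_count` in at least one
#'   negative pool.
#' @export
in_negative_pools <- function(seq, negative_pools, min_count = 1) {
  stopifnot(length(seq) == 1)
  check_polarity(negative_pools, "negative")
  any(vapply(negative_pools, function(p) {
    i <- match(seq, p$records$sequence)
    !is.na(i) && p$records$count[i] >= min_count
  }, logical(1)))
}

#' Library homologs of a candidate sequence
#'
#' Finds unselected-library sequences that are near-identical to the
#' candidate: identity strictly greater than `identity_threshold` with a
#' library count of at least `min_count`. A nonempty result suggests the
#' candidate's abundance is inherited from library bias rather than
#' selection. Identities are computed on random regions.
#'
#' @param seq Candidate random-region sequence.
#' @param library A [round_pool()] for the unselected library (R0).
#' @param identity_threshold Strict lower bound on identity (default 0.85).
#' @param min_count Minimum library count considered (default 5).
#' @return data.frame with columns `library_sequence`, `identity`,
#'   `library_count`, possibly zero rows ("no homologs in the library").
#' @export
library_homologs <- function(seq, library, identity_threshold = 0.85,
                             min_count = 5) {
  stopifnot(length(seq) == 1, inherits(library, "round_pool"))
  if (library$polarity != "unselected") {
    stop("library pool must be the unselected round (polarity 'unselected')")
  }
  lib <- library$records[library$records$count >= min_count, , drop = FALSE]
  if (nrow(lib) == 0) {
    return(data.frame(library_sequence = character(), identity = numeric(),
                      library_count = integer(), stringsAsFactors = FALSE))
  }
  ids <- identity_to_set(seq, lib$sequence)
  keep <- ids > identity_threshold
  out <- data.frame(library_sequence = lib$sequence[keep],
                    identity = ids[keep],
                    library_count = lib$count[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$identity, out$library_sequence, method = "radix"), ,
      drop = FALSE]
}

#' Flag parasitic sequences
#'
#' Parasites are sequences abundant in both positive and negative pools:
#' they persist through counter-selection, indicating enrichment by
#' amplification or nonspecific capture rather than target binding.
#'
#' @param positive_pools,negative_pools Lists of [round_pool()]s of the
#'   respective polarity.
#' @param min_count Count defining "abundant" in a pool (default 100 reads,
#'   i.e. 0.1% at the default simulated depth of 1e5).
#' @return Sorted character vector of flagged sequences (possibly empty).
#' @export
flag_parasites <- function(positive_pools, negative_pools, min_count = 100) {
  check_polarity(positive_pools, "positive")
  check_polarity(negative_pools, "negative")
  if (length(positive_pools) == 0 || length(negative_pools) == 0) {
    return(character(0))
  }
  abundant <- function(p) p$records$sequence[p$records$count >= min_count]
  pos <- unique(unlist(lapply(positive_pools, abundant)))
  neg <- unique(unlist(lapply(negative_pools, abundant)))
  sort(intersect(pos, neg), method = "radix")
}

check_polarity <- function(pools, polarity) {
  ok <- vapply(pools, function(p) {
    inherits(p, "round_pool") && p$polarity == polarity
  }, logical(1))
  if (!all(ok)) stop("all pools must be round_pool objects with polarity '",
                     polarity, "'")
  invisible(TRUE)
}

#' Build a candidate-aptamer table
#'
#' Joins enrichment ranks, cluster sizes, negative-pool and library-homolog
#' flags (and optional externally computed annotation scores) into one row
#' per enriched sequence. Flags annotate rather than delete: sequences hit
#' by the negative-pool or homolog filters stay in the table so the
#' filtering decision is reported, not silent.
#'
#' @param enrichments Output of [rank_by_enrichment()] (possibly truncated
#'   via [top_n_enriched()]); sequences are random regions.
#' @param clusters Optional [greedy_cluster()] result computed on the same
#'   sequences with primers attached (see `fwd`, `rev`).
#' @param negative_pools List of negative-round [round_pool()]s.
#' @param library Unselected-library [round_pool()] for homolog search.
#' @param annotations Optional data.frame with columns `sequence` and
#'   `z_score` (e.g. externally computed binding-potential scores), joined
#'   passively by sequence.
#' @param fwd,rev Primers used to reconstruct full-length sequences for the
#'   cluster join; defaults to [he4_primers()].
#' @param homolog_identity,homolog_min_count Passed to [library_homologs()].
#' @param negative_min_count Passed to [in_negative_pools()].
#' @return data.frame ordered by (round, rank) with columns `id`,
#'   `sequence`, `round`, `rank`, `enrichment`, `cluster_size`,
#'   `in_negative_pool`, `n_library_homologs`, `library_homologs`
#'   (collapsed summary string), `z_score`.
#' @export
build_candidate_table <- function(enrichments, clusters = NULL,
                                  negative_pools = list(), library = NULL,
                                  annotations = NULL,
                                  fwd = he4_primers()[["fwd"]],
                                  rev = he4_primers()[["rev"]],
                                  homolog_identity = 0.85,
                                  homolog_min_count = 5,
                                  negative_min_count = 1) {
  stopifnot(is.data.frame(enrichments))
  n <- nrow(enrichments)
  if (n == 0) {
    warning("empty enrichment table: no candidates to report")
  }
  seqs <- enrichments$sequence
  cluster_size <- rep(NA_integer_, n)
  if (!is.null(clusters) && n > 0) {
    full <- attach_primers(seqs, fwd, rev)
    i <- match(full, clusters$sequence)
    if (anyNA(i)) {
      warning(sum(is.na(i)), " sequence(s) absent from the clustering ",
              "input; cluster_size recorded as NA")
    }
    cluster_size <- clusters$size[i]
  }
  in_neg <- rep(FALSE, n)
  if (length(negative_pools) && n > 0) {
    in_neg <- vapply(seqs, in_negative_pools, logical(1),
                     negative_pools = negative_pools,
                     min_count = negative_min_count, USE.NAMES = FALSE)
  }
  n_hom <- rep(0L, n)
  hom_txt <- rep("", n)
  if (!is.null(library) && n > 0) {
    for (k in seq_len(n)) {
      h <- library_homologs(seqs[k], library, homolog_identity,
                            homolog_min_count)
      n_hom[k] <- nrow(h)
      if (nrow(h)) {
        hom_txt[k] <- paste(sprintf("%s(id=%.3f,n=%d)", h$library_sequence,
                                    h$identity, h$library_count),
                            collapse = ";")
      }
    }
  }
  z <- rep(NA_real_, n)
  if (!is.null(annotations) && n > 0) {
    stopifnot(all(c("sequence", "z_score") %in% names(annotations)))
    z <- annotations$z_score[match(seqs, annotations$sequence)]
  }
  out <- data.frame(
    id = if (n) paste0(enrichments$target_round, ".", enrichments$rank)
         else character(),
    sequence = seqs,
    round = enrichments$target_round,
    rank = enrichments$rank,
    enrichment = enrichments$fold_enrichment,
    cluster_size = cluster_size,
    in_negative_pool = in_neg,
    n_library_homologs = n_hom,
    library_homologs = hom_txt,
    z_score = z,
    stringsAsFactors = FALSE)
  out <- out[order(out$round, out$rank, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
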