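#' Global alignment of two sequences
#'
#' Optimal end-to-end (Needleman-Wunsch) alignment under linear gap costs.
#' Among alignments of optimal score the one with the most matched columns
#' is chosen, then the one with the fewest gap columns, so the reported
#' identity is deterministic. `N` never matches, not even another `N`.
#'
#' @param a,b Non-empty sequences.
#' @param match,mismatch,gap Column scores (defaults 1 / -1 / -2; gaps are
#'   linear, no opening/extension distinction).
#' @return `global_alignment`: list with `score`, `matches`, `mismatches`,
#'   `gaps` (gap columns), `columns` (alignment length) and `identity`.
#'   `global_identity`: the identity alone, `matches / columns`, in `[0, 1]`.
#' @examples
#' global_identity("ACGTACGTACGT", "ACGTACGTACGT")  # 1
#' global_alignment("ACGTA", "ACGA")                # one deletion
#' @export
global_alignment <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(length(a) == 1, length(b) == 1, nchar(a) > 0, nchar(b) > 0)
  align_global_cpp(toupper(a), toupper(b), match, mismatch, gap)
}

#' @rdname global_alignment
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  global_alignment(a, b, match, mismatch, gap)$identity
}

# identity of one sequence against many, vectorized in C++
identity_to_set <- function(a, bs, match = 1, mismatch = -1, gap = -2) {
  if (length(bs) == 0) return(numeric(0))
  identity_many_cpp(toupper(a), toupper(bs), match, mismatch, gap)
}

#' Re-attach primers to random regions
#'
#' Clustering operates on full-length sequences (primers attached), whereas
#' enrichment and homolog search use random regions only.
#'
#' @param regions Character vector of random regions.
#' @param fwd,rev Primer sequences in read orientation.
#' @return `paste0(fwd, regions, rev)`.
#' @export
attach_primers <- function(regions, fwd, rev) {
  paste0(fwd, regions, rev)
}

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are scanned in count-descending order (ties lexicographic).
#' The first sequence seeds cluster 1; each subsequent sequence is compared
#' to the representatives of all existing clusters and joins the cluster of
#' highest identity if that identity is `>= threshold` (ties: lowest cluster
#' id); otherwise it seeds a new cluster. This reimplements the
#' CD-HIT-EST-style usage (identity threshold 0.8, assignment by highest
#' identity across all clusters) with exact alignments instead of word
#' filters.
#'
#' @param sequences Character vector (typically full-length, primers
#'   attached).
#' @param counts Read counts used for the scan order (default all 1).
#' @param threshold Identity threshold in `(0, 1]` (default 0.8).
#' @inheritParams global_alignment
#' @return data.frame of class `selex_clusters` with columns `cluster_id`,
#'   `sequence`, `count`, `identity` (to the cluster representative),
#'   `is_representative`, `size`; attribute `representatives` holds the seed
#'   sequence of each cluster.
#' @examples
#' cl <- greedy_cluster(c("ACGTACGTAC", "ACGTACGTAC", "TTTTTGGGGG"))
#' cluster_sizes(cl)
#' @export
greedy_cluster <- function(sequences, counts = NULL, threshold = 0.8,
                           match = 1, mismatch = -1, gap = -2) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sequences) == 0) {
    out <- data.frame(cluster_id = integer(), sequence = character(),
                      count = integer(), identity = numeric(),
                      is_representative = logical(), size = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "representatives") <- character(0)
    attr(out, "threshold") <- threshold
    class(out) <- c("selex_clusters", "data.frame")
    return(out)
  }
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences))
  ord <- order(-counts, sequences, method = "radix")
  seqs <- toupper(sequences[ord])
  cnts <- counts[ord]
  n <- length(seqs)
  reps <- character(0)
  assign_id <- integer(n)
  ident <- numeric(n)
  is_rep <- logical(n)
  for (k in seq_len(n)) {
    if (length(reps)) {
      ids <- identity_many_cpp(seqs[k], reps, match, mismatch, gap)
      best <- which.max(ids)  # ties -> lowest cluster id
      if (ids[best] >= threshold) {
        assign_id[k] <- best
        ident[k] <- ids[best]
        next
      }
    }
    reps <- c(reps, seqs[k])
    assign_id[k] <- length(reps)
    ident[k] <- 1
    is_rep[k] <- TRUE
  }
  sizes <- tabulate(assign_id, nbins = length(reps))
  out <- data.frame(cluster_id = assign_id, sequence = seqs, count = cnts,
                    identity = ident, is_representative = is_rep,
                    size = sizes[assign_id], stringsAsFactors = FALSE)
  attr(out, "representatives") <- reps
  attr(out, "threshold") <- threshold
  class(out) <- c("selex_clusters", "data.frame")
  out
}

#' Cluster sizes and membership lookups
#'
#' @param clusters A [greedy_cluster()] result.
#' @return `cluster_sizes`: integer vector, size of each cluster in id
#'   order. `cluster_size_of`: size of the cluster containing `seq` (error
#'   if the sequence was not clustered).
#' @export
cluster_sizes <- function(clusters) {
  stopifnot(inherits(clusters, "selex_clusters"))
  tabulate(clusters$cluster_id,
           nbins = length(attr(clusters, "representatives")))
}

#' @rdname cluster_sizes
#' @param seq Sequence to look up (must have been part of the clustered
#'   input).
#' @export
cluster_size_of <- function(seq, clusters) {
  stopifnot(inherits(clusters, "selex_clusters"), length(seq) == 1)
  i <- match(toupper(seq), clusters$sequence)
  if (is.na(i)) stop("sequence was not part of the clustered input: ", seq)
  clusters$size[i]
}
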