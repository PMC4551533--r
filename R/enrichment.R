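#' Relative frequency table of a pool
#'
#' @param pool A non-empty [round_pool()].
#' @return data.frame with columns `sequence` and `frequency`
#'   (`count / total_reads`); frequencies sum to 1. The round label is kept
#'   in attribute `round_label`.
#' @export
frequency_table <- function(pool) {
  stopifnot(inherits(pool, "round_pool"))
  if (pool$total_reads < 1) stop("frequency table of an empty pool")
  out <- data.frame(sequence = pool$records$sequence,
                    frequency = pool$records$count / pool$total_reads,
                    stringsAsFactors = FALSE)
  attr(out, "round_label") <- pool$round_label
  out
}

#' Fold enrichment of one sequence between two rounds
#'
#' The ratio of the sequence's read fraction in the target round to its read
#' fraction in the reference round, computed on random regions only. A
#' reference count below `pseudocount` is replaced by `pseudocount` so that
#' sequences absent from the reference get a finite, conservatively large
#' enrichment.
#'
#' @param seq Random-region sequence; must be present in `target`.
#' @param ref,target Reference and target [round_pool()]s (e.g. the
#'   unselected library R0 and a later selection round).
#' @param pseudocount Reads; floor applied to the reference count (default 1).
#' @return Positive number `[c_t/T_t] / [max(c_r, pseudocount)/T_r]`.
#' @examples
#' r0 <- round_pool(data.frame(sequence = c("AA", "CC"), count = c(10, 990)),
#'                  "R0", "unselected")
#' r3 <- round_pool(data.frame(sequence = c("AA", "CC"), count = c(40, 1960)),
#'                  "R3", "positive")
#' fold_enrichment("AA", r0, r3)
#' @export
fold_enrichment <- function(seq, ref, target, pseudocount = 1) {
  stopifnot(inherits(ref, "round_pool"), inherits(target, "round_pool"),
            length(seq) == 1)
  it <- match(seq, target$records$sequence)
  if (is.na(it)) stop("sequence not present in target round ",
                      target$round_label)
  ir <- match(seq, ref$records$sequence)
  cr <- if (is.na(ir)) 0 else ref$records$count[ir]
  crp <- max(cr, pseudocount)
  if (crp <= 0) stop("zero reference count with pseudocount < 1: ",
                     "fold enrichment undefined")
  (target$records$count[it] / target$total_reads) /
    (crp / ref$total_reads)
}

#' Rank all target-round sequences by fold enrichment
#'
#' One record per sequence present in the target round, sorted by fold
#' enrichment descending. Ties are broken by higher target count, then by
#' sequence (lexicographic), so ranks are a deterministic function of the
#' two pools.
#'
#' @inheritParams fold_enrichment
#' @return data.frame with columns `sequence`, `ref_round`, `target_round`,
#'   `f_ref` (pseudocounted reference frequency), `f_target`,
#'   `fold_enrichment`, `ref_count`, `target_count`, `rank` (1 = most
#'   enriched). `fold_enrichment == f_target / f_ref` holds exactly.
#' @export
rank_by_enrichment <- function(ref, target, pseudocount = 1) {
  stopifnot(inherits(ref, "round_pool"), inherits(target, "round_pool"))
  if (ref$total_reads < 1 || target$total_reads < 1) {
    stop("both pools must be non-empty")
  }
  tc <- target$records$count
  i <- match(target$records$sequence, ref$records$sequence)
  cr <- ifelse(is.na(i), 0L, ref$records$count[i])
  crp <- pmax(cr, pseudocount)
  if (any(crp <= 0)) {
    stop("zero reference count with pseudocount < 1: ",
         "fold enrichment undefined")
  }
  f_ref <- crp / ref$total_reads
  f_target <- tc / target$total_reads
  fe <- f_target / f_ref
  ord <- order(-fe, -tc, target$records$sequence, method = "radix")
  out <- data.frame(sequence = target$records$sequence[ord],
                    ref_round = ref$round_label,
                    target_round = target$round_label,
                    f_ref = f_ref[ord], f_target = f_target[ord],
                    fold_enrichment = fe[ord],
                    ref_count = cr[ord], target_count = tc[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Keep the top-n most enriched records
#'
#' @param records Output of [rank_by_enrichment()].
#' @param n Number of records to keep (default 1000, the clustering input
#'   size used downstream).
#' @return The first `min(n, nrow(records))` records in rank order.
#' @export
top_n_enriched <- function(records, n = 1000) {
  stopifnot(is.data.frame(records), n >= 1)
  records[seq_len(min(n, nrow(records))), , drop = FALSE]
}
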