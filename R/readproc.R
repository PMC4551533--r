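#' Read a FASTQ file
#'
#' Minimal strict reader for 4-line-per-record FASTQ (plain or gzip).
#' Malformed input (line count not divisible by 4, header/separator tags
#' missing, quality shorter or longer than the bases) raises an error naming
#' the offending record.
#'
#' @param path Path to a FASTQ file; `.gz` suffix triggers decompression.
#' @return A data.frame with columns `read_id`, `bases` (uppercase), and
#'   `quality`, one row per record, in file order. Empty file gives zero rows.
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (truncated record ",
         length(lines) %/% 4 + 1, ")")
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(data.frame(read_id = character(), bases = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  ids   <- lines[seq(1, by = 4, length.out = n)]
  bases <- toupper(lines[seq(2, by = 4, length.out = n)])
  plus  <- lines[seq(3, by = 4, length.out = n)]
  qual  <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) stop("malformed FASTQ: record ", bad[1],
                        " does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ: record ", bad[1],
                        " missing '+' separator line")
  bad <- which(nchar(qual) != nchar(bases))
  if (length(bad)) stop("malformed FASTQ: quality/sequence length mismatch",
                        " at record ", bad[1])
  bad <- which(nchar(bases) == 0)
  if (length(bad)) stop("malformed FASTQ: empty sequence at record ", bad[1])
  data.frame(read_id = sub("^@", "", ids), bases = bases, quality = qual,
             stringsAsFactors = FALSE)
}

#' Trim selection primers from amplicon reads
#'
#' The forward primer is matched as an anchored prefix allowing at most
#' `floor(mismatch_frac * nchar(fwd))` substitutions and no indels; the
#' reverse-primer region is then scanned left to right after the forward
#' primer with the analogous budget, and the leftmost hit wins. The returned
#' random region is everything strictly between the two primer matches; the
#' reverse primer and all downstream bases (sequencing adaptors included) are
#' discarded. `N` always counts as a mismatch. Regions whose length falls
#' outside `length_target +/- length_tol` get status `bad_length`.
#'
#' @param reads Character vector of read sequences (uppercase A/C/G/T/N).
#' @param fwd,rev Forward primer and reverse-primer region, read orientation.
#' @param mismatch_frac Substitution budget as a fraction of primer length
#'   (default 0.05, i.e. 1 substitution for a 20-nt primer).
#' @param length_target,length_tol Accepted random-region length window
#'   (default 25 +/- 2).
#' @return data.frame with columns `status` (one of `ok`,
#'   `no_forward_primer`, `no_reverse_primer`, `bad_length`) and
#'   `random_region` (`NA` unless status is `ok`).
#' @examples
#' p <- he4_primers()
#' region <- strrep("A", 25)
#' trim_primers(paste0(p["fwd"], region, p["rev"], "ACGT"), p["fwd"], p["rev"])
#' @export
trim_primers <- function(reads, fwd, rev, mismatch_frac = 0.05,
                         length_target = 25, length_tol = 2) {
  stopifnot(is.character(reads), nchar(fwd) > 0, nchar(rev) > 0,
            mismatch_frac >= 0, mismatch_frac < 0.5)
  res <- trim_reads_cpp(toupper(reads), toupper(fwd), toupper(rev),
                        mismatch_frac, as.integer(length_target),
                        as.integer(length_tol))
  codes <- c("ok", "no_forward_primer", "no_reverse_primer", "bad_length")
  data.frame(status = codes[res$status + 1L],
             random_region = res$region, stringsAsFactors = FALSE)
}

#' Random-region length filter
#'
#' @param region Character vector of trimmed random regions.
#' @param target,tol Accepted window `target +/- tol` (default 25 +/- 2).
#' @return Logical vector, `TRUE` where the length is inside the window.
#' @export
filter_length <- function(region, target = 25, tol = 2) {
  stopifnot(all(nchar(region) > 0))
  len <- nchar(region)
  len >= target - tol & len <= target + tol
}

#' Construct a per-round sequence pool
#'
#' A round pool is the deduplicated sequence/count table for one SELEX round,
#' with records ordered by count descending (ties broken lexicographically).
#'
#' @param records data.frame with columns `sequence` and `count`.
#' @param round_label Round label, e.g. `"R0"`, `"R2+"`, `"R3-"`.
#' @param polarity One of `"positive"`, `"negative"`, `"unselected"`.
#' @param fraction Which fraction was sequenced: `"bound"` or `"free"`.
#' @return Object of class `round_pool`.
#' @export
round_pool <- function(records, round_label,
                       polarity = c("positive", "negative", "unselected"),
                       fraction = c("bound", "free")) {
  polarity <- match.arg(polarity)
  fraction <- match.arg(fraction)
  stopifnot(is.data.frame(records),
            all(c("sequence", "count") %in% names(records)))
  records <- records[, c("sequence", "count")]
  records$count <- as.integer(records$count)
  if (nrow(records)) {
    stopifnot(all(records$count >= 1L),
              !anyDuplicated(records$sequence))
    ord <- order(-records$count, records$sequence, method = "radix")
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(round_label = round_label, polarity = polarity,
                 fraction = fraction, records = records,
                 total_reads = sum(records$count)),
            class = "round_pool")
}

#' @export
print.round_pool <- function(x, ...) {
  cat(sprintf("<round_pool %s (%s, %s fraction)>\n", x$round_label,
              x$polarity, x$fraction))
  cat(sprintf("  %d reads, %d unique sequences\n",
              x$total_reads, nrow(x$records)))
  if (nrow(x$records)) {
    cat(sprintf("  duplication: %.1f%% of reads\n", duplication_percent(x)))
    print(head(x$records, 5))
  }
  invisible(x)
}

#' Deduplicate trimmed regions into a round pool
#'
#' One record per distinct sequence with its read count; records sorted by
#' count descending, ties broken lexicographically ascending.
#'
#' @param regions Character vector of accepted random regions.
#' @inheritParams round_pool
#' @return A [round_pool()] whose `total_reads` equals `length(regions)`.
#' @examples
#' dedup_counts(c("AAA", "AAA", "CCC"), "R1", "positive")
#' @export
dedup_counts <- function(regions, round_label,
                         polarity = c("positive", "negative", "unselected"),
                         fraction = c("bound", "free")) {
  if (length(regions) == 0) {
    return(round_pool(data.frame(sequence = character(), count = integer()),
                      round_label, polarity, fraction))
  }
  r <- rle(sort(regions, method = "radix"))
  round_pool(data.frame(sequence = r$values, count = r$lengths,
                        stringsAsFactors = FALSE),
             round_label, polarity, fraction)
}

#' Sequence duplication percentage of a pool
#'
#' `fraction_of_total` is the FastQC-style definition,
#' `100 * (total - unique) / total`; `relative_to_unique` is the literal
#' duplicates-relative-to-unique reading, `100 * (total - unique) / unique`.
#'
#' @param pool A [round_pool()] with at least one read.
#' @param mode Which definition to use (default `fraction_of_total`).
#' @return Percentage as a single number.
#' @examples
#' p <- dedup_counts(c(rep("AAA", 20), strrep(c("C","G","T","AC"), 5)), "R1",
#'                   "positive")
#' duplication_percent(p)
#' duplication_percent(p, "relative_to_unique")
#' @export
duplication_percent <- function(pool,
                                mode = c("fraction_of_total",
                                         "relative_to_unique")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "round_pool"))
  if (pool$total_reads < 1) {
    stop("duplication_percent is undefined for an empty pool")
  }
  n_unique <- nrow(pool$records)
  dup <- pool$total_reads - n_unique
  switch(mode,
         fraction_of_total = 100 * dup / pool$total_reads,
         relative_to_unique = 100 * dup / n_unique)
}

#' Process one round's FASTQ into a clean pool
#'
#' Runs [read_fastq()], [trim_primers()] and [dedup_counts()] and assembles a
#' per-round processing report (read counts by failure mode, duplication).
#'
#' @inheritParams read_fastq
#' @inheritParams trim_primers
#' @inheritParams round_pool
#' @return List with elements `pool` (a [round_pool()]) and `report` (named
#'   list: `reads_in`, `reads_accepted`, `n_no_forward_primer`,
#'   `n_no_reverse_primer`, `n_bad_length`, `duplication_percent`).
#' @export
process_fastq <- function(path, fwd, rev, round_label,
                          polarity = c("positive", "negative", "unselected"),
                          fraction = c("bound", "free"),
                          mismatch_frac = 0.05, length_target = 25,
                          length_tol = 2) {
  reads <- read_fastq(path)
  tr <- trim_primers(reads$bases, fwd, rev, mismatch_frac, length_target,
                     length_tol)
  ok <- tr$status == "ok"
  pool <- dedup_counts(tr$random_region[ok], round_label, polarity, fraction)
  report <- list(
    reads_in = nrow(reads),
    reads_accepted = sum(ok),
    n_no_forward_primer = sum(tr$status == "no_forward_primer"),
    n_no_reverse_primer = sum(tr$status == "no_reverse_primer"),
    n_bad_length = sum(tr$status == "bad_length"),
    duplication_percent = if (sum(ok)) duplication_percent(pool) else NA_real_
  )
  list(pool = pool, report = report)
}

#' Write / read a pool as TSV
#'
#' Plain two-column TSV (`sequence`, `count`); round metadata is supplied at
#' read time.
#'
#' @param pool A [round_pool()].
#' @param path Output/input TSV path.
#' @inheritParams round_pool
#' @return `write_pool_tsv` returns `path` invisibly; `read_pool_tsv` a
#'   [round_pool()].
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "round_pool"))
  write.table(pool$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path, round_label,
                          polarity = c("positive", "negative", "unselected"),
                          fraction = c("bound", "free")) {
  records <- read.delim(path, stringsAsFactors = FALSE)
  round_pool(records, round_label, polarity, fraction)
}
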