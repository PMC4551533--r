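fq_lines <- function(recs) {
  unlist(lapply(seq_along(recs), function(i) {
    c(paste0("@read", i), recs[i], "+", strrep("I", nchar(recs[i])))
  }))
}

test_that("read_fastq returns records in file order and validates structure", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fq_lines(c("ACGT", "GGCC")), tmp)
  r <- read_fastq(tmp)
  expect_equal(nrow(r), 2)
  expect_equal(r$bases, c("ACGT", "GGCC"))
  expect_equal(r$read_id, c("read1", "read2"))

  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fastq(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)
  expect_error(read_fastq(bad), "record 1")

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), trunc)
  expect_error(read_fastq(trunc), "multiple of 4")

  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt"); writeLines(fq_lines("ACGTA"), con); close(con)
  expect_equal(read_fastq(gz)$bases, "ACGTA")
})

test_that("primer trimming enforces the substitution budget with no indels", {
  p <- he4_primers()
  region <- strrep("ACGTA", 5)  # 25 nt
  read <- paste0(p["fwd"], region, p["rev"], "ACGTACGT")
  r <- trim_primers(read, p["fwd"], p["rev"])
  expect_equal(r$status, "ok")
  expect_equal(r$random_region, region)

  # 1 substitution in the 20-nt forward primer: budget floor(0.05*20) = 1
  one <- read; substr(one, 5, 5) <- "C"
  # 2 substitutions: budget exceeded
  two <- one; substr(two, 9, 9) <- "C"
  r <- trim_primers(c(one, two), p["fwd"], p["rev"])
  expect_equal(r$status, c("ok", "no_forward_primer"))
  expect_equal(r$random_region[1], region)

  # 1 substitution inside the reverse primer region is tolerated too
  rev_pos <- nchar(p["fwd"]) + 25 + 3  # third base of the rev region (T)
  rev1 <- read
  substr(rev1, rev_pos, rev_pos) <- "G"
  r <- trim_primers(rev1, p["fwd"], p["rev"])
  expect_equal(r$status, "ok")
  expect_equal(r$random_region, region)

  # missing reverse primer
  norev <- paste0(p["fwd"], region, "ACGTACGTACGTACGTACGT")
  expect_equal(trim_primers(norev, p["fwd"], p["rev"])$status,
               "no_reverse_primer")

  # N counts as a mismatch: 1 N in fwd is within budget, N plus a
  # substitution is not
  n1 <- read; substr(n1, 2, 2) <- "N"
  n2 <- n1; substr(n2, 11, 11) <- "T"
  r <- trim_primers(c(n1, n2), p["fwd"], p["rev"])
  expect_equal(r$status, c("ok", "no_forward_primer"))
})

test_that("trimming is invariant to bases after the reverse primer", {
  p <- he4_primers()
  region <- strrep("GATTC", 5)
  tails <- c("", "A", "AGATCGGAAGAGC", strrep("N", 40))
  reads <- paste0(p["fwd"], region, p["rev"], tails)
  r <- trim_primers(reads, p["fwd"], p["rev"])
  expect_true(all(r$status == "ok"))
  expect_true(all(r$random_region == region))
})

test_that("length filter accepts 25 +/- 2 only", {
  expect_true(filter_length(strrep("A", 25)))
  expect_true(filter_length(strrep("A", 27)))
  expect_true(filter_length(strrep("A", 23)))
  expect_false(filter_length(strrep("A", 28)))
  expect_false(filter_length(strrep("A", 22)))
  # and trim_primers reports the same window as bad_length
  p <- he4_primers()
  reads <- paste0(p["fwd"], c(strrep("A", 28), strrep("A", 22),
                              strrep("A", 23)), p["rev"])
  expect_equal(trim_primers(reads, p["fwd"], p["rev"])$status,
               c("bad_length", "bad_length", "ok"))
})

test_that("dedup_counts counts, sorts by count then lexicographically", {
  pool <- dedup_counts(c("AAA", "AAA", "CCC"), "R1", "positive")
  expect_equal(pool$records$sequence, c("AAA", "CCC"))
  expect_equal(pool$records$count, c(2L, 1L))
  expect_equal(pool$total_reads, 3L)

  tie <- dedup_counts(c("CCC", "AAA"), "R1", "positive")
  expect_equal(tie$records$sequence, c("AAA", "CCC"))

  ten <- dedup_counts(rep("GGG", 10), "R1", "positive")
  expect_equal(nrow(ten$records), 1)
  expect_equal(ten$records$count, 10L)

  empty <- dedup_counts(character(0), "R1", "positive")
  expect_equal(empty$total_reads, 0L)
})

test_that("duplication percentage implements both definitions", {
  # 100 reads, 80 unique
  pool <- pool_of(setNames(c(rep(2L, 20), rep(1L, 60)),
                           random_dna(80, 10)))
  expect_equal(duplication_percent(pool), 20)
  expect_equal(duplication_percent(pool, "relative_to_unique"), 25)

  one <- pool_of(c(AAA = 100L))
  expect_equal(duplication_percent(one), 99)

  distinct <- pool_of(setNames(rep(1L, 5), random_dna(5, 8)))
  expect_equal(duplication_percent(distinct), 0)
  expect_equal(duplication_percent(distinct, "relative_to_unique"), 0)

  expect_error(duplication_percent(dedup_counts(character(0), "R0",
                                                "unselected")),
               "empty")
})

test_that("duplication strictly increases as copies of an existing sequence accrue", {
  set.seed(41)
  seqs <- random_dna(50, 12)
  regions <- seqs
  prev <- duplication_percent(dedup_counts(regions, "R1", "positive"))
  for (k in 1:5) {
    regions <- c(regions, seqs[1])
    cur <- duplication_percent(dedup_counts(regions, "R1", "positive"))
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("count conservation: accepted + rejected = total", {
  p <- he4_primers()
  set.seed(42)
  good <- random_dna(30, 25)
  reads <- c(paste0(p["fwd"], good, p["rev"], "ACGT"),
             paste0("TTTTTTTTTTTTTTTTTTTT", strrep("A", 25), p["rev"]),
             paste0(p["fwd"], strrep("A", 40), p["rev"]))
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fq_lines(reads), tmp)
  res <- process_fastq(tmp, p["fwd"], p["rev"], "R1", "positive")
  rep <- res$report
  expect_equal(rep$reads_in, length(reads))
  expect_equal(rep$reads_accepted + rep$n_no_forward_primer +
                 rep$n_no_reverse_primer + rep$n_bad_length, rep$reads_in)
  expect_equal(res$pool$total_reads, rep$reads_accepted)
  expect_equal(sum(res$pool$records$count), rep$reads_accepted)
})

test_that("pool TSV round-trips", {
  pool <- pool_of(c(ACGTA = 5L, GGGTT = 2L, AAAAA = 2L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(pool, tmp)
  back <- read_pool_tsv(tmp, "R1", "positive")
  expect_equal(back$records, pool$records)
  expect_equal(back$total_reads, pool$total_reads)
})
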