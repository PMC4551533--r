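test_that("library generation matches configured base composition", {
  cfg <- sim_config(seed = 3, depth_per_round = 1e4, parasite_count = 0,
                    adaptor_fraction = 0,
                    base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  lib <- make_library(cfg)
  expect_equal(lib$pool$total_reads, 1e4)
  reads <- rep(lib$pool$records$sequence, lib$pool$records$count)
  tab <- table(strsplit(paste(reads, collapse = ""), "")[[1]])
  freq <- tab / sum(tab)
  n <- sum(tab)
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3.5 * sigma))

  # thymine-biased scenario
  cfgT <- sim_config(seed = 3, depth_per_round = 1e4, parasite_count = 0,
                     adaptor_fraction = 0,
                     base_probs = c(A = 0.2, C = 0.2, G = 0.2, T = 0.4))
  libT <- make_library(cfgT)
  readsT <- rep(libT$pool$records$sequence, libT$pool$records$count)
  tabT <- table(strsplit(paste(readsT, collapse = ""), "")[[1]])
  expect_equal(unname(tabT["T"] / sum(tabT)), 0.4, tolerance = 0.02)
})

test_that("ground truth labels every sequence and flags spikes", {
  cfg <- sim_config(seed = 4, depth_per_round = 2e4)
  lib <- make_library(cfg)
  expect_setequal(lib$truth$sequence, lib$pool$records$sequence)
  expect_equal(sum(lib$truth$is_parasite), cfg$parasite_count)
  expect_true(all(lib$truth$Kd[lib$truth$is_motif] == cfg$Kd_motif))
  expect_true(all(lib$truth$Kd[!lib$truth$is_motif] == cfg$Kd_bg))
  # adaptor-derived contaminant dominates the library (the L1 signature)
  ad <- substr(cfg$adaptor, 1, cfg$region_length)
  expect_equal(lib$pool$records$sequence[1], ad)
  expect_equal(lib$pool$records$count[1],
               round(cfg$adaptor_fraction * cfg$depth_per_round))
  expect_error(make_library(sim_config(motif = strrep("A", 30))), "motif")
})

test_that("selection rounds conserve depth and are seed-reproducible", {
  cfg <- sim_config(seed = 8, n_rounds = 2, depth_per_round = 1e4)
  sim1 <- simulate_selex(cfg)
  sim2 <- simulate_selex(cfg)
  expect_identical(sim1$pools, sim2$pools)
  expect_true(all(vapply(sim1$pools, function(p) p$total_reads,
                         numeric(1)) == 1e4))
  expect_equal(names(sim1$pools), c("R0", "R1", "R2+", "R2-"))
  expect_equal(sim1$pools[["R2-"]]$polarity, "negative")
})

test_that("motif carriers gain frequency each positive round", {
  # strong-selection regime: Kd_motif << protein concentration << Kd_bg
  cfg <- sim_config(seed = 15, n_rounds = 3, depth_per_round = 5e4,
                    Kd_motif = 1, negative_rounds = integer(0))
  sim <- simulate_selex(cfg)
  motif_seqs <- sim$truth$sequence[sim$truth$is_motif]
  agg <- vapply(sim$pools, function(p) {
    i <- p$records$sequence %in% motif_seqs
    sum(p$records$count[i]) / p$total_reads
  }, numeric(1))
  expect_true(all(diff(agg) > 0))
  # and duplication grows under selective pressure
  dup <- vapply(sim$pools, duplication_percent, numeric(1))
  expect_true(all(diff(dup) > 0))
})

test_that("negative rounds do not boost planted binders", {
  cfg <- sim_config(seed = 16, n_rounds = 2, depth_per_round = 5e4)
  sim <- simulate_selex(cfg)
  motif_seqs <- sim$truth$sequence[sim$truth$is_motif]
  freq_of <- function(p) {
    i <- p$records$sequence %in% motif_seqs
    sum(p$records$count[i]) / p$total_reads
  }
  # binder mass may only drift (multinomially) through a negative round,
  # in contrast to the boost a positive round gives
  ratio_neg <- freq_of(sim$pools[["R2-"]]) / freq_of(sim$pools[["R2+"]])
  ratio_pos <- freq_of(sim$pools[["R2+"]]) / freq_of(sim$pools[["R1"]])
  expect_lt(ratio_neg, 1.25)
  expect_gt(ratio_pos, 1.5)
})

test_that("null selection leaves frequencies stable", {
  # no planted affinity, no parasite gain: capture weight is constant, so
  # expected frequencies are unchanged and median enrichment sits near 1.
  # A short region keeps sequence diversity far below the depth, so per-
  # sequence counts are large enough that survivorship (a sequence must be
  # present in the target round to have an enrichment) does not bias the
  # median upward.
  cfg <- sim_config(seed = 17, n_rounds = 2, depth_per_round = 5e4,
                    region_length = 6, motif = "CAGTGC",
                    Kd_motif = 1e6, parasite_pcr_gain = 1,
                    adaptor_fraction = 0)
  sim <- simulate_selex(cfg)
  e <- rank_by_enrichment(sim$pools$R0, sim$pools[["R2+"]])
  expect_equal(median(e$fold_enrichment), 1, tolerance = 0.05)
})

test_that("simulated FASTQ round-trips exactly through read processing", {
  p <- he4_primers()
  cfg <- sim_config(seed = 19, n_rounds = 1, depth_per_round = 2000,
                    negative_rounds = integer(0))
  sim <- simulate_selex(cfg)
  for (lab in names(sim$pools)) {
    pool <- sim$pools[[lab]]
    tmp <- withr::local_tempfile(fileext = ".fastq")
    write_round_fastq(pool, p["fwd"], p["rev"], cfg$adaptor, tmp)
    back <- process_fastq(tmp, p["fwd"], p["rev"], pool$round_label,
                          pool$polarity, pool$fraction)
    expect_equal(back$pool$records, pool$records)
    expect_equal(back$report$reads_accepted, pool$total_reads)
  }
  # empty pool -> valid empty FASTQ
  empty <- dedup_counts(character(0), "R9", "positive")
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_round_fastq(empty, p["fwd"], p["rev"], "", tmp)
  expect_equal(read_fastq(tmp)$bases, character(0))
})

test_that("binding assay simulation is exact at zero noise and reproducible", {
  d0 <- simulate_binding_assay(390, 10, 1, apce_titration(), noise_sd = 0,
                               replicates = 2)
  expect_equal(d0$signal,
               isotherm_signal(d0$T, 10, 390, 1))
  a <- simulate_binding_assay(280, 100, 0.05, anisotropy_titration(),
                              seed = 77)
  b <- simulate_binding_assay(280, 100, 0.05, anisotropy_titration(),
                              seed = 77)
  expect_identical(a, b)
})
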