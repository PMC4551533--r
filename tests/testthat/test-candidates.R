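neg_pool <- function(counts, label = "R2-") {
  pool_of(counts, label, polarity = "negative")
}

test_that("negative-pool membership respects the count threshold", {
  negs <- list(neg_pool(c(AAA = 3L, CCC = 10L), "R2-"),
               neg_pool(c(GGG = 1L), "R3-"))
  expect_false(in_negative_pools("TTT", negs))          # absent everywhere
  expect_true(in_negative_pools("AAA", negs))           # count 3 >= 1
  expect_false(in_negative_pools("AAA", negs, min_count = 5))
  expect_true(in_negative_pools("CCC", negs, min_count = 5))
  expect_error(in_negative_pools("AAA", list(pool_of(c(AAA = 1L)))),
               "polarity")
})

test_that("library homologs use strict identity and minimum count", {
  lib <- pool_of(c(AAAAAAAAAAAAAAAAAAAA = 7L,
                   CCCCCAAAAAAAAAAAAAAA = 100L,
                   GGGGGGGGGGGGGGGGGGGG = 50L,
                   TTTTTTTTTTTTTTTTTTTT = 2L),
                 "R0", polarity = "unselected", fraction = "free")
  # identical sequence at count 7 -> homolog at identity 1
  h <- library_homologs("AAAAAAAAAAAAAAAAAAAA", lib)
  expect_equal(h$library_sequence[1], "AAAAAAAAAAAAAAAAAAAA")
  expect_equal(h$identity[1], 1)
  expect_equal(h$library_count[1], 7L)
  # 15/20 = 0.75 identity relative is below the 0.85 bar
  expect_false("CCCCCAAAAAAAAAAAAAAA" %in% h$library_sequence)
  # identity exactly at the threshold is excluded (strict >)
  h85 <- library_homologs("AAAAAAAAAAAAAAAAAAAA", lib,
                          identity_threshold = 0.75)
  expect_false("CCCCCAAAAAAAAAAAAAAA" %in% h85$library_sequence)
  h_below <- library_homologs("AAAAAAAAAAAAAAAAAAAA", lib,
                              identity_threshold = 0.7499)
  expect_true("CCCCCAAAAAAAAAAAAAAA" %in% h_below$library_sequence)
  # count below min_count is never a homolog even at identity 1
  h2 <- library_homologs("TTTTTTTTTTTTTTTTTTTT", lib)
  expect_equal(nrow(h2), 0)
  expect_error(library_homologs("AAA", pool_of(c(AAA = 9L))), "unselected")
})

test_that("parasites are sequences abundant in both polarities", {
  pos <- list(pool_of(c(P1 = 500L, B1 = 200L, X = 1L), "R2+"),
              pool_of(c(P1 = 800L, P2 = 150L), "R3+"))
  neg <- list(neg_pool(c(P1 = 700L, P2 = 200L, B1 = 5L), "R2-"))
  fl <- flag_parasites(pos, neg, min_count = 100)
  expect_equal(fl, c("P1", "P2"))
  # only-positive sequences are not flagged
  expect_false("B1" %in% fl)
  # empty negative side -> empty set
  expect_equal(flag_parasites(pos, list(), min_count = 100), character(0))
})

test_that("candidate table joins flags, clusters and annotations", {
  p <- he4_primers()
  set.seed(51)
  seqs <- random_dna(6, 25)
  ref <- pool_of(setNames(c(5L, 1L, 1L, 1L, 1L, 200L), seqs),
                 "R0", "unselected", "free")
  tgt <- pool_of(setNames(c(10L, 120L, 80L, 40L, 20L, 190L), seqs), "R3")
  e <- rank_by_enrichment(ref, tgt)
  cl <- greedy_cluster(attach_primers(e$sequence, p["fwd"], p["rev"]),
                       e$target_count)
  negs <- list(neg_pool(setNames(c(300L, 2L), c(seqs[6], seqs[2]))))
  ann <- data.frame(sequence = seqs[2], z_score = 10.75)
  tab <- build_candidate_table(e, cl, negs, ref, ann,
                               fwd = p["fwd"], rev = p["rev"])
  expect_equal(nrow(tab), 6)
  expect_equal(tab$rank, 1:6)
  # the most enriched sequence leads the table
  expect_equal(tab$sequence[1], seqs[2])
  expect_equal(tab$n_library_homologs[1], 0L)
  expect_true(tab$in_negative_pool[1])  # count 2 >= default min_count 1
  tab5 <- build_candidate_table(e, cl, negs, ref, ann,
                                fwd = p["fwd"], rev = p["rev"],
                                negative_min_count = 5)
  expect_false(tab5$in_negative_pool[1])
  # library-abundant sequence carries a homolog flag (A3/L1 pattern)
  i6 <- match(seqs[6], tab$sequence)
  expect_true(tab$n_library_homologs[i6] >= 1)
  expect_true(tab$in_negative_pool[i6])
  # annotation joined passively, ranks untouched
  expect_equal(tab$z_score[1], 10.75)
  expect_true(all(is.na(tab$z_score[-1])))
  expect_equal(tab$cluster_size,
               vapply(attach_primers(tab$sequence, p["fwd"], p["rev"]),
                      cluster_size_of, integer(1), clusters = cl,
                      USE.NAMES = FALSE))
})

test_that("candidate table warns on empty input and missing cluster entries", {
  e <- rank_by_enrichment(pool_of(c(AAA = 1L), "R0", "unselected"),
                          pool_of(c(AAA = 5L), "R3"))
  expect_warning(build_candidate_table(e[0, ]), "empty")
  cl <- greedy_cluster("TTTTTTTTTT")  # does not contain the candidate
  expect_warning(tab <- build_candidate_table(e, cl), "absent")
  expect_true(is.na(tab$cluster_size[1]))
})

test_that("clean candidates have no negative-pool or homolog hits on simulated data", {
  cfg <- sim_config(seed = 9, n_rounds = 3, depth_per_round = 2e4)
  sim <- simulate_selex(cfg)
  e <- top_n_enriched(rank_by_enrichment(sim$pools$R0, sim$pools[["R3+"]]),
                      30)
  negs <- unname(sim$pools[c("R2-", "R3-")])
  # at simulated depth the nonspecific carryover scatters every abundant
  # sequence into the negative pools at low counts, so presence is judged
  # at the same abundance threshold used for parasite flagging
  min_neg <- 50
  tab <- build_candidate_table(e, clusters = NULL, negative_pools = negs,
                               library = sim$pools$R0,
                               negative_min_count = min_neg)
  clean <- tab[!tab$in_negative_pool & tab$n_library_homologs == 0, ]
  expect_gt(nrow(clean), 0)
  for (s in clean$sequence) {
    expect_false(in_negative_pools(s, negs, min_count = min_neg))
    expect_equal(nrow(library_homologs(s, sim$pools$R0)), 0)
  }
})

test_that("parasite recovery on planted simulation", {
  cfg <- sim_config(seed = 13, n_rounds = 3, depth_per_round = 5e4)
  sim <- simulate_selex(cfg)
  pos <- unname(sim$pools[c("R1", "R2+", "R3+")])
  neg <- unname(sim$pools[c("R2-", "R3-")])
  fl <- flag_parasites(pos, neg, min_count = 100)
  planted <- sim$truth$sequence[sim$truth$is_parasite]
  binders <- sim$truth$sequence[sim$truth$is_motif]
  expect_gte(mean(planted %in% fl), 0.9)
  expect_equal(sum(binders %in% fl), 0)
})
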