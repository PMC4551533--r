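#!/usr/bin/env Rscript
# Step 3: compute fold enrichment of every sequence in each positive round
# against the unselected library (pseudocount 1 for sequences unseen in R0),
# rank, keep the top 1000 per round, and cluster them at identity 0.8 with
# primers re-attached (greedy scan, assignment by highest identity across
# all cluster representatives).

suppressPackageStartupMessages(library(selexenrich))

manifest <- read.delim("results/sim/manifest.tsv", stringsAsFactors = FALSE)
p <- he4_primers()
safe_label <- function(lab) gsub("[+]", "pos", gsub("[-]", "neg", lab))
load_pool <- function(m) {
  read_pool_tsv(file.path("results/pools", paste0(safe_label(m$label),
                                                  ".tsv")),
                m$label, m$polarity, m$fraction)
}

r0 <- load_pool(manifest[manifest$polarity == "unselected", ])
dir.create("results/enrichment", showWarnings = FALSE)
dir.create("results/clusters", showWarnings = FALSE)

pos <- manifest[manifest$polarity == "positive", ]
for (k in seq_len(nrow(pos))) {
  m <- pos[k, ]
  pool <- load_pool(m)
  e <- rank_by_enrichment(r0, pool, pseudocount = 1)
  write.table(e, file.path("results/enrichment",
                           paste0(safe_label(m$label), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- top_n_enriched(e, 1000)
  cl <- greedy_cluster(attach_primers(top$sequence, p["fwd"], p["rev"]),
                       top$target_count, threshold = 0.8)
  write.table(as.data.frame(cl),
              file.path("results/clusters",
                        paste0(safe_label(m$label), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- cluster_sizes(cl)
  message(m$label, ": top enrichment ", round(e$fold_enrichment[1], 1),
          "x; ", length(sizes), " clusters over the top ", nrow(top),
          " sequences (largest cluster ", max(sizes), ")")
}
message("wrote per-round enrichment tables and clusterings under results/")
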