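#!/usr/bin/env Rscript
# Step 2: read each round's FASTQ, strip the selection primers (5% mismatch
# budget, no indels), keep random regions of 25 +/- 2 nt, deduplicate into
# per-round count tables, and summarize read yield and sequence duplication
# per round -- the simulated analog of the study's sequencing summary table.

suppressPackageStartupMessages(library(selexenrich))

manifest <- read.delim("results/sim/manifest.tsv", stringsAsFactors = FALSE)
p <- he4_primers()
pool_dir <- "results/pools"
dir.create(pool_dir, showWarnings = FALSE, recursive = TRUE)

rows <- lapply(seq_len(nrow(manifest)), function(k) {
  m <- manifest[k, ]
  res <- process_fastq(m$path, p["fwd"], p["rev"], m$label, m$polarity,
                       m$fraction)
  safe <- gsub("[+]", "pos", gsub("[-]", "neg", m$label))
  write_pool_tsv(res$pool, file.path(pool_dir, paste0(safe, ".tsv")))
  data.frame(label = m$label, polarity = m$polarity, fraction = m$fraction,
             reads_in = res$report$reads_in,
             reads_accepted = res$report$reads_accepted,
             n_unique = nrow(res$pool$records),
             duplication_percent = round(res$report$duplication_percent, 1),
             stringsAsFactors = FALSE)
})
summary_tab <- do.call(rbind, rows)
write.table(summary_tab, "results/round_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("per-round processing summary:")
print(summary_tab, row.names = FALSE)
message("duplication rises from ",
        summary_tab$duplication_percent[1], "% (unselected) to ",
        summary_tab$duplication_percent[nrow(summary_tab)],
        "% (final round), the qualitative signature of a selection that is",
        " converging; compare selex_reported_rounds() for the reported",
        " experimental trend (11.8% to 37.7%).")
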