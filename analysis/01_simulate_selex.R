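#!/usr/bin/env Rscript
# Step 1: generate a synthetic 5-round CE-SELEX experiment with known ground
# truth (planted 8-nt motif binders at Kd 390 nM, 5 amplification parasites,
# 5% adaptor-derived library contamination, thymine-biased base composition)
# and write per-round FASTQ files the way a sequencing facility would deliver
# them. Downstream steps only see the FASTQ files; the truth table is kept
# aside for the final evaluation.

suppressPackageStartupMessages(library(selexenrich))

out_dir <- "results/sim"
fastq_dir <- file.path(out_dir, "fastq")
dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42, n_rounds = 5)
message("simulating ", cfg$n_rounds, " positive rounds (+ negatives after ",
        paste(cfg$negative_rounds, collapse = ", "), ") at depth ",
        cfg$depth_per_round, " reads/round")
sim <- simulate_selex(cfg)

p <- he4_primers()
manifest <- do.call(rbind, lapply(names(sim$pools), function(lab) {
  safe <- gsub("[+]", "pos", gsub("[-]", "neg", lab))
  path <- file.path(fastq_dir, paste0(safe, ".fastq"))
  write_round_fastq(sim$pools[[lab]], p["fwd"], p["rev"], cfg$adaptor, path)
  data.frame(label = lab, polarity = sim$pools[[lab]]$polarity,
             fraction = sim$pools[[lab]]$fraction, path = path,
             stringsAsFactors = FALSE)
}))
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_binders <- sum(sim$truth$is_motif)
message("library: ", nrow(sim$truth), " distinct sequences, ",
        n_binders, " motif carriers (",
        round(100 * n_binders / nrow(sim$truth), 2), "%), ",
        sum(sim$truth$is_parasite), " parasites")
message("wrote ", nrow(manifest), " FASTQ files and the manifest to ",
        out_dir)
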