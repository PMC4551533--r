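#' Configuration for the synthetic CE-SELEX simulator
#'
#' Defines the study conditions emulated by the generator: a thymine-biased
#' "random" 25-nt library, a planted binding motif whose carriers get a
#' selectable Kd, parasitic sequences with an amplification advantage,
#' adaptor-derived contamination, and a multi-round selection with
#' decreasing target concentration (default schedule 50, 10, 5, 1, 0.5 nM)
#' and counter-selection (negative) rounds after rounds 2 and 3.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param n_rounds Number of positive selection rounds (default 5).
#' @param depth_per_round Reads sequenced per round (default 1e5).
#' @param region_length Random-region length, nt (default 25).
#' @param base_probs Per-position base probabilities A/C/G/T; the default
#'   carries the thymine bias observed in ostensibly random libraries.
#' @param motif Planted binding motif (default an 8-mer).
#' @param motif_max_mismatch Mismatches tolerated for a motif hit (default 1).
#' @param Kd_motif Dissociation constant of motif carriers, nM (default 390,
#'   a representative selected-aptamer affinity).
#' @param Kd_bg Background (non-binder) Kd, nM (default 1e6, effectively no
#'   affinity at nanomolar target).
#' @param protein_conc_schedule Target concentration per positive round, nM.
#' @param negative_protein_conc Tag-only concentration in negative rounds.
#' @param dna_conc DNA concentration entering the quadratic bound-fraction
#'   calculation, nM.
#' @param capture_efficiency Fraction of bound molecules recovered.
#' @param background_carryover Nonspecific carryover weight added to every
#'   sequence.
#' @param parasite_count Number of planted parasitic sequences.
#' @param parasite_reads Initial library reads of each parasite.
#' @param parasite_pcr_gain Multiplier on the parasites' carryover term,
#'   modeling their amplification/capture advantage in every round.
#' @param adaptor Sequencing adaptor appended after the reverse primer in
#'   written FASTQ; its prefix also seeds the adaptor-derived library
#'   contaminant.
#' @param adaptor_fraction Fraction of library reads that are the
#'   adaptor-derived contaminant sequence (default 0.05).
#' @param negative_rounds Positive-round indices after which a negative
#'   round is run (default `c(2, 3)`).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_rounds = 5, depth_per_round = 1e5,
                       region_length = 25,
                       base_probs = c(A = 0.22, C = 0.22, G = 0.22,
                                      T = 0.34),
                       motif = "CAGTGCGT", motif_max_mismatch = 1,
                       Kd_motif = 390, Kd_bg = 1e6,
                       protein_conc_schedule = c(50, 10, 5, 1, 0.5),
                       negative_protein_conc = 50, dna_conc = 50,
                       capture_efficiency = 0.5,
                       background_carryover = 0.01,
                       parasite_count = 5, parasite_reads = 50,
                       parasite_pcr_gain = 4,
                       adaptor = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       adaptor_fraction = 0.05,
                       negative_rounds = c(2, 3)) {
  stopifnot(length(base_probs) == 4, all(base_probs >= 0),
            abs(sum(base_probs) - 1) < 1e-8,
            Kd_motif > 0, Kd_bg > 0, depth_per_round >= 1,
            n_rounds >= 1, region_length >= 1,
            capture_efficiency >= 0, capture_efficiency <= 1,
            background_carryover >= 0, adaptor_fraction >= 0,
            adaptor_fraction < 1, parasite_count >= 0, parasite_reads >= 1,
            parasite_pcr_gain >= 0)
  if (nchar(motif) > region_length) {
    stop("motif is longer than the random region")
  }
  if (length(protein_conc_schedule) < n_rounds) {
    stop("protein_conc_schedule shorter than n_rounds")
  }
  structure(list(seed = as.integer(seed), n_rounds = n_rounds,
                 depth_per_round = as.integer(depth_per_round),
                 region_length = region_length, base_probs = base_probs,
                 motif = toupper(motif),
                 motif_max_mismatch = motif_max_mismatch,
                 Kd_motif = Kd_motif, Kd_bg = Kd_bg,
                 protein_conc_schedule = protein_conc_schedule,
                 negative_protein_conc = negative_protein_conc,
                 dna_conc = dna_conc,
                 capture_efficiency = capture_efficiency,
                 background_carryover = background_carryover,
                 parasite_count = parasite_count,
                 parasite_reads = parasite_reads,
                 parasite_pcr_gain = parasite_pcr_gain,
                 adaptor = toupper(adaptor),
                 adaptor_fraction = adaptor_fraction,
                 negative_rounds = negative_rounds),
            class = "sim_config")
}

# TRUE where the motif occurs with at most max_mismatch substitutions
motif_hits <- function(seqs, motif, max_mismatch) {
  if (length(seqs) == 0) return(logical(0))
  as.logical(Biostrings::vcountPattern(
    motif, Biostrings::DNAStringSet(seqs),
    max.mismatch = max_mismatch, fixed = TRUE) > 0)
}

random_regions <- function(n, length, base_probs) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE,
                     prob = base_probs), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate the unselected library with ground truth
#'
#' Draws `depth_per_round` reads i.i.d. with per-position base
#' probabilities, spikes in the planted parasites and the adaptor-derived
#' contaminant, and assigns every distinct sequence its ground-truth Kd:
#' `Kd_motif` if it carries the motif (within the mismatch budget), else
#' `Kd_bg`. Parasite sequences are drawn to be motif-free so affinity and
#' amplification advantage stay disentangled.
#'
#' @param config A [sim_config()].
#' @return List with `pool` (the R0 [round_pool()], polarity `unselected`,
#'   `free` fraction) and `truth` (data.frame: `sequence`, `Kd`,
#'   `is_motif`, `is_parasite`).
#' @export
make_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  depth <- config$depth_per_round
  L <- config$region_length
  n_adapt <- round(config$adaptor_fraction * depth)
  n_par <- config$parasite_count * config$parasite_reads
  n_rand <- depth - n_adapt - n_par
  if (n_rand <= 0) stop("depth too small for the configured spikes")
  rand_seqs <- random_regions(n_rand, L, config$base_probs)
  par_seqs <- character(config$parasite_count)
  for (i in seq_len(config$parasite_count)) {
    repeat {
      s <- random_regions(1, L, config$base_probs)
      if (!motif_hits(s, config$motif, config$motif_max_mismatch)) {
        par_seqs[i] <- s
        break
      }
    }
  }
  adaptor_region <- substr(paste0(config$adaptor, strrep("A", L)), 1, L)
  regions <- c(rand_seqs,
               rep(par_seqs, each = config$parasite_reads),
               rep(adaptor_region, n_adapt))
  pool <- dedup_counts(regions, "R0", "unselected", "free")
  seqs <- pool$records$sequence
  is_motif <- motif_hits(seqs, config$motif, config$motif_max_mismatch)
  truth <- data.frame(sequence = seqs,
                      Kd = ifelse(is_motif, config$Kd_motif, config$Kd_bg),
                      is_motif = is_motif,
                      is_parasite = seqs %in% par_seqs,
                      stringsAsFactors = FALSE)
  list(pool = pool, truth = truth)
}

#' Simulate one selection round
#'
#' Every sequence gets a capture weight
#' `capture_efficiency * bound_fraction + background_carryover`, where the
#' bound fraction comes from the quadratic ligand-depletion model
#' ([complex_concentration()]) at the round's protein concentration. In
#' positive rounds the sequence's own Kd applies; in negative rounds all
#' planted binders are treated as background (`Kd_bg`), since the tag-only
#' target gives them no advantage. Parasites have their carryover term
#' multiplied by `parasite_pcr_gain` in every round. The next pool is a
#' multinomial sample of `depth_per_round` reads with probabilities
#' proportional to `count * weight` (the capture-weighted, i.e. sequenced,
#' fraction).
#'
#' @param pool Current [round_pool()] (non-empty).
#' @param truth Ground-truth table from [make_library()].
#' @param protein_conc Target concentration this round, nM.
#' @param is_negative Whether this is a counter-selection round.
#' @param config The [sim_config()].
#' @param round_label Label for the output pool.
#' @return The next [round_pool()], polarity `positive` or `negative`,
#'   `bound` fraction, with exactly `depth_per_round` reads.
#' @export
simulate_round <- function(pool, truth, protein_conc, is_negative, config,
                           round_label = "R1") {
  stopifnot(inherits(pool, "round_pool"), inherits(config, "sim_config"),
            pool$total_reads >= 1)
  i <- match(pool$records$sequence, truth$sequence)
  if (anyNA(i)) stop("pool contains sequences without ground truth")
  kd <- if (is_negative) rep(config$Kd_bg, length(i)) else truth$Kd[i]
  bf <- complex_concentration(config$dna_conc, protein_conc, kd) /
    config$dna_conc
  carry <- rep(config$background_carryover, length(i))
  carry[truth$is_parasite[i]] <- config$background_carryover *
    config$parasite_pcr_gain
  w <- config$capture_efficiency * bf + carry
  pr <- pool$records$count * w
  if (all(pr <= 0)) stop("simulation error: all capture weights are zero")
  cnt <- as.vector(rmultinom(1, config$depth_per_round, pr))
  keep <- cnt > 0
  round_pool(data.frame(sequence = pool$records$sequence[keep],
                        count = cnt[keep], stringsAsFactors = FALSE),
             round_label,
             polarity = if (is_negative) "negative" else "positive",
             fraction = "bound")
}

#' Simulate a full multi-round selection
#'
#' Chains [make_library()] and [simulate_round()]: each round's output seeds
#' the next, passing through negative rounds where configured (as in a real
#' selection, where counter-selected DNA is the input of the following
#' positive round). Pools are labeled `R0`, `R1`, `R2+`, `R2-`, ... in the
#' paper-style convention (a `+` suffix only where a matching negative
#' round exists).
#'
#' @param config A [sim_config()].
#' @return List with `pools` (named list of [round_pool()]s, R0 first),
#'   `truth`, and `config`.
#' @export
simulate_selex <- function(config) {
  lib <- make_library(config)  # seeds the RNG from config$seed
  pools <- list(R0 = lib$pool)
  cur <- lib$pool
  for (k in seq_len(config$n_rounds)) {
    has_neg <- k %in% config$negative_rounds
    lab <- if (has_neg) paste0("R", k, "+") else paste0("R", k)
    cur <- simulate_round(cur, lib$truth, config$protein_conc_schedule[k],
                          FALSE, config, lab)
    pools[[lab]] <- cur
    if (has_neg) {
      nlab <- paste0("R", k, "-")
      cur <- simulate_round(cur, lib$truth, config$negative_protein_conc,
                            TRUE, config, nlab)
      pools[[nlab]] <- cur
    }
  }
  list(pools = pools, truth = lib$truth, config = config)
}

#' Write a pool as a synthetic FASTQ file
#'
#' Each sequence is emitted `count` times as
#' `fwd + region + rev + adaptor` with constant quality (`I`), so the file
#' round-trips exactly through [process_fastq()].
#'
#' @param pool A [round_pool()].
#' @param fwd,rev Primers in read orientation.
#' @param adaptor Downstream adaptor appended after the reverse primer
#'   (may be `""`).
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_round_fastq <- function(pool, fwd, rev, adaptor = "", path) {
  stopifnot(inherits(pool, "round_pool"))
  reads <- rep(pool$records$sequence, pool$records$count)
  n <- length(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (n == 0) {
    writeLines(character(0), con)
    return(invisible(path))
  }
  full <- paste0(fwd, reads, rev, adaptor)
  lines <- character(4 * n)
  lines[seq(1, by = 4, length.out = n)] <-
    paste0("@", pool$round_label, "_", seq_len(n))
  lines[seq(2, by = 4, length.out = n)] <- full
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <- strrep("I", nchar(full))
  writeLines(lines, con)
  invisible(path)
}

#' Default titration designs
#'
#' Protein concentration grids emulating the two affinity assays: affinity
#' probe CE titrates 0-240 nM at 10 nM probe; fluorescence anisotropy
#' titrates 0-750 nM at 100 nM probe.
#'
#' @return Numeric vector of protein concentrations in nM.
#' @export
apce_titration <- function() c(0, 10, 20, 40, 80, 120, 160, 200, 240)

#' @rdname apce_titration
#' @export
anisotropy_titration <- function() c(0, 25, 50, 100, 200, 350, 500, 750)

#' Simulate a noisy binding titration
#'
#' Signals are [isotherm_signal()] values plus Gaussian noise with standard
#' deviation `noise_sd * constant` (relative to the saturating amplitude).
#'
#' @param Kd,A,constant True model parameters (nM, nM, signal units).
#' @param T_grid Protein concentrations, nM (see [apce_titration()]).
#' @param noise_sd Relative noise level (default 0.02).
#' @param replicates Measurements per concentration (default 2).
#' @param seed Optional seed for reproducibility.
#' @param form Isotherm form, see [isotherm_signal()].
#' @return data.frame with columns `T`, `signal`, `replicate`.
#' @export
simulate_binding_assay <- function(Kd, A, constant,
                                   T_grid = apce_titration(),
                                   noise_sd = 0.02, replicates = 2,
                                   seed = NULL,
                                   form = c("as_printed",
                                            "fraction_bound")) {
  form <- match.arg(form)
  stopifnot(Kd > 0, A > 0, constant > 0, replicates >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  T <- rep(T_grid, each = replicates)
  mu <- isotherm_signal(T, A, Kd, constant, form)
  data.frame(T = T,
             signal = mu + rnorm(length(T), sd = noise_sd * constant),
             replicate = rep(seq_len(replicates), times = length(T_grid)))
}
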