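#' Pipeline configuration
#'
#' Bundles the round manifest and every threshold of the analysis so a
#' single object drives [run_pipeline()]. Defaults are the standard
#' pipeline parameters: 5% primer mismatch tolerance with no indels, a
#' 25 +/- 2 length window, clustering identity 0.8 on primer-attached
#' sequences, library-homolog identity 0.85 at >= 5 counts, top-1000
#' clustering input, pseudocount 1.
#'
#' @param manifest data.frame with columns `label`, `polarity`
#'   (`positive` / `negative` / `unselected`), `fraction`
#'   (`bound` / `free`), `path` (FASTQ file). Exactly one row must be
#'   `unselected`.
#' @param fwd,rev Primer sequences in read orientation (defaults
#'   [he4_primers()]).
#' @param mismatch_frac,length_target,length_tol See [trim_primers()].
#' @param cluster_threshold,top_n See [greedy_cluster()], [top_n_enriched()].
#' @param homolog_identity,homolog_min_count See [library_homologs()].
#' @param pseudocount See [rank_by_enrichment()].
#' @param parasite_min_count See [flag_parasites()].
#' @param negative_min_count See [in_negative_pools()].
#' @param candidate_top_n Enrichment records per round carried into the
#'   candidate table (default 100).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest,
                            fwd = he4_primers()[["fwd"]],
                            rev = he4_primers()[["rev"]],
                            mismatch_frac = 0.05, length_target = 25,
                            length_tol = 2, cluster_threshold = 0.8,
                            top_n = 1000, homolog_identity = 0.85,
                            homolog_min_count = 5, pseudocount = 1,
                            parasite_min_count = 100,
                            negative_min_count = 1,
                            candidate_top_n = 100) {
  stopifnot(is.data.frame(manifest),
            all(c("label", "polarity", "fraction", "path") %in%
                  names(manifest)))
  if (sum(manifest$polarity == "unselected") != 1) {
    stop("manifest must contain exactly one unselected round")
  }
  structure(list(manifest = manifest, fwd = fwd, rev = rev,
                 mismatch_frac = mismatch_frac,
                 length_target = length_target, length_tol = length_tol,
                 cluster_threshold = cluster_threshold, top_n = top_n,
                 homolog_identity = homolog_identity,
                 homolog_min_count = homolog_min_count,
                 pseudocount = pseudocount,
                 parasite_min_count = parasite_min_count,
                 negative_min_count = negative_min_count,
                 candidate_top_n = candidate_top_n),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: FASTQ processing per round, fold-enrichment ranking
#' of every positive round against the unselected library, greedy
#' clustering of the top-n enriched sequences per round (primers
#' re-attached), parasite flagging across polarities, and candidate-table
#' construction with negative-pool and library-homolog annotation. All
#' stages are pure functions of the inputs and configuration, so reruns on
#' identical inputs are identical.
#'
#' @param config A [pipeline_config()].
#' @param annotations Optional data.frame (`sequence`, `z_score`) joined
#'   into the candidate table.
#' @param out_dir Optional directory; when given, every intermediate table
#'   is persisted as TSV.
#' @return List with `pools` (named list), `round_summary` (per-round
#'   reads/duplication table), `enrichments` (named list of
#'   [rank_by_enrichment()] tables), `clusters` (named list), `parasites`
#'   (character vector), and `candidates` (combined candidate table with a
#'   `is_parasite` column).
#' @export
run_pipeline <- function(config, annotations = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- config$manifest
  missing_files <- !file.exists(man$path)
  if (any(missing_files)) {
    stop("stage readproc: missing FASTQ file(s): ",
         paste(man$path[missing_files], collapse = ", "))
  }
  pools <- list()
  summaries <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    res <- process_fastq(man$path[k], config$fwd, config$rev,
                         man$label[k], man$polarity[k], man$fraction[k],
                         config$mismatch_frac, config$length_target,
                         config$length_tol)
    pools[[man$label[k]]] <- res$pool
    summaries[[k]] <- data.frame(
      label = man$label[k], polarity = man$polarity[k],
      fraction = man$fraction[k], reads_in = res$report$reads_in,
      reads_accepted = res$report$reads_accepted,
      n_unique = nrow(res$pool$records),
      duplication_percent = res$report$duplication_percent,
      stringsAsFactors = FALSE)
  }
  round_summary <- do.call(rbind, summaries)
  library_pool <- pools[[man$label[man$polarity == "unselected"]]]
  positives <- pools[man$label[man$polarity == "positive"]]
  negatives <- pools[man$label[man$polarity == "negative"]]

  enrichments <- list()
  clusters <- list()
  cand_parts <- list()
  for (lab in names(positives)) {
    e <- rank_by_enrichment(library_pool, positives[[lab]],
                            config$pseudocount)
    enrichments[[lab]] <- e
    top <- top_n_enriched(e, config$top_n)
    full <- attach_primers(top$sequence, config$fwd, config$rev)
    clusters[[lab]] <- greedy_cluster(full, top$target_count,
                                      config$cluster_threshold)
    cand_parts[[lab]] <- build_candidate_table(
      top_n_enriched(e, config$candidate_top_n), clusters[[lab]],
      negatives, library_pool, annotations,
      fwd = config$fwd, rev = config$rev,
      homolog_identity = config$homolog_identity,
      homolog_min_count = config$homolog_min_count,
      negative_min_count = config$negative_min_count)
  }
  parasites <- flag_parasites(unname(positives), unname(negatives),
                              config$parasite_min_count)
  candidates <- do.call(rbind, c(cand_parts, list(make.row.names = FALSE)))
  if (!is.null(candidates) && nrow(candidates)) {
    candidates$is_parasite <- candidates$sequence %in% parasites
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(round_summary, file.path(out_dir, "round_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (lab in names(pools)) {
      write_pool_tsv(pools[[lab]],
                     file.path(out_dir, paste0("pool_", gsub("[+]", "pos",
                       gsub("[-]", "neg", lab)), ".tsv")))
    }
    for (lab in names(enrichments)) {
      safe <- gsub("[+]", "pos", gsub("[-]", "neg", lab))
      write.table(enrichments[[lab]],
                  file.path(out_dir, paste0("enrichment_", safe, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(clusters[[lab]]),
                  file.path(out_dir, paste0("clusters_", safe, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(candidates, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(parasites, file.path(out_dir, "parasites.txt"))
  }
  list(pools = pools, round_summary = round_summary,
       enrichments = enrichments, clusters = clusters,
       parasites = parasites, candidates = candidates)
}
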