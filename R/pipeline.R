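# --- config-driven pipeline orchestration ----------------------------------

#' Build a pipeline run configuration
#'
#' @param genome,gff3,de_table,peaks,motif_library input file paths (the
#'   motif library defaults to the bundled known-CRE file).
#' @param out_dir output directory.
#' @param promoter_bp promoter window for enrichment scans (default 1000).
#' @param peak_promoter_bp promoter width for peak categorisation (default
#'   5000).
#' @param de_q DE significance cutoff (default 0.1).
#' @param discovery_q FDR threshold for discovered k-mers (default 0.05).
#' @param match_fdr FDR cutoff for motif-library matches (default 0.01).
#' @param kmin,kmax k-mer length bounds for discovery (defaults 6 and 12).
#' @param n_shuffles shuffles for the motif-comparison null (default 999).
#' @param seed integer seed for every random draw of the run.
#' @param max_compare_kmers cap on significant k-mers per group passed to
#'   motif comparison (default 10).
#' @return a list of class `run_config`.
#' @export
run_config <- function(genome, gff3, de_table, peaks,
                       motif_library = system.file("extdata",
                                                   "known_cres.tsv",
                                                   package = "touchcre"),
                       out_dir = "touchcre_run",
                       promoter_bp = 1000L, peak_promoter_bp = 5000L,
                       de_q = 0.1, discovery_q = 0.05, match_fdr = 0.01,
                       kmin = 6L, kmax = 12L, n_shuffles = 999L, seed = 1L,
                       max_compare_kmers = 10L) {
  cfg <- list(genome = genome, gff3 = gff3, de_table = de_table,
              peaks = peaks, motif_library = motif_library,
              out_dir = out_dir, promoter_bp = as.integer(promoter_bp),
              peak_promoter_bp = as.integer(peak_promoter_bp),
              de_q = de_q, discovery_q = discovery_q, match_fdr = match_fdr,
              kmin = as.integer(kmin), kmax = as.integer(kmax),
              n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
              max_compare_kmers = as.integer(max_compare_kmers))
  if (cfg$kmin > cfg$kmax) stopf("kmin must be <= kmax")
  for (th in c("de_q", "discovery_q", "match_fdr"))
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1)
      stopf("%s must lie in (0, 1)", th)
  structure(cfg, class = "run_config")
}

#' Read a flat key-value run configuration file (YAML)
#'
#' @param path path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full cis-regulatory analysis pipeline
#'
#' Stages, in order: promoter extraction, known-CRE scanning, enrichment,
#' per-group k-mer discovery, motif comparison, peak annotation, and the
#' binding-by-DE cross-tabulation. Every output TSV carries comment headers
#' recording the package version, seed and parameters; coordinates are
#' 0-based half-open. A JSON manifest listing the configuration and the
#' md5 sums of every output makes the run re-runnable and verifiable. All
#' randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `status` (0 on success), `manifest_path`
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name)
    message(sprintf("[touchcre %7.1fs] %s", proc.time()[["elapsed"]] - t0,
                    name))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("touchcre %s", as.character(packageVersion("touchcre"))),
           sprintf("seed: %d", config$seed),
           sprintf("promoter_bp: %d; peak_promoter_bp: %d; de_q: %g; discovery_q: %g; match_fdr: %g; kmin: %d; kmax: %d; n_shuffles: %d",
                   config$promoter_bp, config$peak_promoter_bp, config$de_q,
                   config$discovery_q, config$match_fdr, config$kmin,
                   config$kmax, config$n_shuffles),
           "coordinates: 0-based half-open")
  outfile <- function(x) file.path(config$out_dir, x)
  outputs <- character()
  emit <- function(df, name, extra = character()) {
    p <- write_tsv_commented(df, outfile(name), c(hdr, extra))
    outputs <<- c(outputs, p)
    p
  }

  log_stage("genome")
  genome <- stage("genome", read_fasta(config$genome))
  log_stage("annotation")
  annot <- stage("annotation", read_gff3(config$gff3))
  log_stage("de_table")
  de <- stage("de_table", read_de_table(config$de_table))
  log_stage("peaks")
  peaks <- stage("peaks", read_bed(config$peaks))
  library_motifs <- stage("motif_library",
                          read_motif_library(config$motif_library))

  log_stage("promoters")
  promoters <- stage("promoters",
                     extract_promoters(genome, annot, config$promoter_bp,
                                       anchor = "tss"))
  background <- promoters$entries$gene_id
  groups <- stage("de_groups", gene_groups_from_de(de, config$de_q))

  log_stage("known-CRE scan")
  scan_res <- stage("scan", lapply(library_motifs, scan_promoters,
                                   promoters = promoters))
  log_stage("known-CRE enrichment")
  enr <- stage("enrichment",
               enrich_motifs(scan_res, groups, background,
                             q_threshold = 0.05))
  emit(enr, "known_cre_enrichment.tsv")
  mat <- enrichment_neglog10_matrix(enr)
  emit(cbind(data.frame(motif = rownames(mat), stringsAsFactors = FALSE),
             as.data.frame(mat)), "known_cre_neglog10p_matrix.tsv")

  log_stage("k-mer discovery")
  seqs <- stats::setNames(promoters$entries$sequence,
                          promoters$entries$gene_id)
  kmer_reports <- stage("discovery", lapply(groups, function(g) {
    fg_ids <- g$gene_ids
    if (!length(fg_ids)) return(NULL)
    forest <- discover_kmers(seqs[fg_ids], seqs[setdiff(background, fg_ids)],
                             kmin = config$kmin, kmax = config$kmax,
                             q_threshold = config$discovery_q)
    cbind(data.frame(group = g$label, stringsAsFactors = FALSE),
          forest$report)
  }))
  kmer_tab <- do.call(rbind, kmer_reports)
  rownames(kmer_tab) <- NULL
  emit(kmer_tab, "kmer_report.tsv")

  log_stage("motif comparison")
  matches <- stage("compare", {
    res <- lapply(names(groups), function(lb) {
      kt <- kmer_tab[kmer_tab$group == lb & kmer_tab$significant, ,
                     drop = FALSE]
      if (!nrow(kt)) return(NULL)
      kt <- kt[seq_len(min(nrow(kt), config$max_compare_kmers)), ,
               drop = FALSE]
      cbind(data.frame(group = lb, stringsAsFactors = FALSE),
            compare_kmers_to_library(kt$kmer, library_motifs,
                                     n_shuffles = config$n_shuffles,
                                     seed = config$seed,
                                     match_fdr = config$match_fdr))
    })
    out <- do.call(rbind, res)
    if (is.null(out))
      out <- data.frame(group = character(), query = character(),
                        target = character(), offset = integer(),
                        orientation = character(), score = numeric(),
                        empirical_p = numeric(), q_value = numeric(),
                        matched = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
  emit(matches, "motif_matches.tsv")

  log_stage("peak annotation")
  annotated <- stage("annotate",
                     annotate_peaks(peaks, annot, config$peak_promoter_bp))
  emit(annotated, "annotated_peaks.tsv")
  emit(feature_distribution(annotated), "feature_distribution.tsv")
  prof <- tss_profile(annotated, annot)
  emit(data.frame(bin_start = prof$breaks[-length(prof$breaks)],
                  bin_end = prof$breaks[-1], count = prof$counts,
                  density = prof$density),
       "tss_profile.tsv",
       sprintf("mean_transcript_length (TTS mark): %.1f",
               prof$mean_transcript_length))

  log_stage("crosstab")
  xtab <- stage("crosstab", crosstab_targets(annotated, de, config$de_q))
  emit(xtab, "target_crosstab.tsv",
       "gene body = any genic category including UTRs")

  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(
    list(package = "touchcre",
         version = as.character(packageVersion("touchcre")),
         config = unclass(config),
         outputs = data.frame(
           file = basename(outputs),
           md5 = unname(tools::md5sum(outputs)),
           stringsAsFactors = FALSE)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done")
  invisible(list(status = 0L, manifest_path = manifest_path,
                 enrichment = enr, kmer_report = kmer_tab,
                 motif_matches = matches, annotated_peaks = annotated,
                 crosstab = xtab))
}
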