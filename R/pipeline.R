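## End-to-end orchestration: simulate/ingest -> tail prep -> cleavage calling
## -> internal-priming filter -> clustering -> profiling -> PAS assignment ->
## APA annotation, with a run report mirroring the study's summary tables,
## plus validation of a synthetic run against its truth tables.

.genome_md5 <- function(genome) {
  genome <- .genome_strings(genome)
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pA-site discovery pipeline
#'
#' Executes every stage in order and assembles a run report with the
#' evidence-processing counters (raw reads, tailed reads, mapped reads, pA
#' clusters per source and their additive total), cluster member-count
#' fractions, the PAS usage table, feature-category fractions and per-gene
#' site-count class fractions. Rerunning with the same input and seed is
#' bit-identical.
#'
#' @param input One of: a \code{\link{sim_config}} (the dataset is simulated
#'   first), a simulation list from \code{\link{simulate_pa_dataset}}, or a
#'   named list of file paths \code{list(genome=, annotation=, reads=,
#'   alignments=)} (FASTA / GFF3 / FASTA-FASTQ / SAM-BAM).
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written (clusters BED + members, assignment/usage/profile TSVs, report).
#' @param min_tail Minimum tail length for \code{\link{prepare_reads}}.
#' @param merge_distance Cluster merge distance, nt.
#' @param filter A \code{\link{filter_config}}.
#' @param halfwidth Flank half width for profiling.
#' @param pas_window PAS search window, nt upstream.
#' @param scan_range Hexamer scan range.
#' @param gc Background GC fraction for the chi-square background model;
#'   defaults to the simulation's \code{gc_content} (synthetic input) or
#'   0.364.
#' @param restore_single_a Apply \code{\link{restore_templated_a}} after
#'   cleavage calling (default TRUE).
#' @param merge_sources Pool evidence sources before clustering instead of
#'   clustering per source and adding totals.
#' @return A list of class \code{"pa_run"} with all stage outputs and
#'   \code{report}.
#' @export
run_pa_pipeline <- function(input, out_dir = NULL,
                            min_tail = 10L, merge_distance = 20L,
                            filter = filter_config(), halfwidth = 100L,
                            pas_window = 40L, scan_range = c(-50L, -1L),
                            gc = NULL, restore_single_a = TRUE,
                            merge_sources = FALSE) {
  sim <- NULL
  if (inherits(input, "sim_config")) {
    sim <- simulate_pa_dataset(input)
    input <- sim
  }
  if (is.list(input) && !is.null(input$config) && !is.null(input$reads)) {
    sim <- input
    genome <- sim$genome
    reads_df <- data.frame(read_id = sim$reads$read_id,
                           sequence = sim$reads$sequence,
                           source_tag = sim$reads$source_tag,
                           stringsAsFactors = FALSE)
    aln <- sim$alignments
    models <- load_annotation(annotation_granges(sim))
    if (is.null(gc)) gc <- sim$config$gc_content
  } else {
    genome <- .genome_strings(Biostrings::readDNAStringSet(input$genome))
    reads_df <- input$reads
    aln <- read_alignment_file(input$alignments)
    models <- load_annotation(input$annotation)
    if (is.null(gc)) gc <- 0.364
  }

  prep <- prepare_reads(reads_df, min_tail = min_tail)
  tailed_ids <- prep$calls$read_id

  called <- call_cleavage_events(aln)
  ev <- called$events
  ev <- ev[ev$read_id %in% tailed_ids, , drop = FALSE]
  # source tags travel with the prep calls for file input
  tag <- prep$calls$source_tag[match(ev$read_id, prep$calls$read_id)]
  if (!all(is.na(tag))) ev$source_tag <- tag
  n_mapped <- table(factor(ev$source_tag,
                           levels = unique(prep$calls$source_tag)))

  if (restore_single_a) ev <- restore_templated_a(ev, genome)
  ev <- internal_priming_filter(ev, genome, filter)
  kept <- ev[ev$keep, , drop = FALSE]

  clusters <- cluster_events(kept, merge_distance = merge_distance,
                             merge_sources = merge_sources)
  site_summary <- summarize_sites(clusters)

  flanks <- extract_flanks(clusters, genome, halfwidth = halfwidth)
  mono <- nucleotide_profile(flanks, order = 1L)
  di <- nucleotide_profile(flanks, order = 2L)
  scan <- hexamer_position_scan(flanks, scan_range = scan_range)
  pascalls <- assign_pas(flanks, window = pas_window)
  usage <- usage_frequency_table(pascalls)
  dse <- dse_enrichment(mono, di, gc = gc)

  assignments <- assign_feature(clusters, models)
  apa <- summarize_gene_apa(assignments, clusters)
  catfrac <- category_fractions(assignments)
  chrom_sum <- chromosome_summary(clusters, models)

  sources <- as.character(prep$stats$source_tag)
  per_source_clusters <- table(factor(clusters$source_tag,
                                      levels = unique(clusters$source_tag)))
  table1 <- data.frame(
    source = sources,
    raw_reads = prep$stats$raw_count,
    tailed_reads = prep$stats$tailed_count,
    mapped_reads = as.integer(n_mapped[sources]),
    pa_clusters = as.integer(table(factor(clusters$source_tag,
                                          levels = sources))),
    stringsAsFactors = FALSE)
  report <- list(
    table1 = table1,
    total_pa_clusters = nrow(clusters),
    member_fractions = site_summary$member_fractions,
    usage = usage,
    category_fractions = catfrac,
    class_fractions = apa$class_fractions,
    apa_fraction = apa$apa_fraction,
    dse = dse)

  run <- structure(list(
    prep = prep, events = ev, clusters = clusters,
    site_summary = site_summary, flanks = flanks, mono_profile = mono,
    di_profile = di, scan = scan, pascalls = pascalls, usage = usage,
    assignments = assignments, apa = apa, category_fractions = catfrac,
    chromosome_summary = chrom_sum, report = report, gc = gc,
    genome_md5 = .genome_md5(genome)), class = "pa_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write all pipeline outputs to a directory
#'
#' @param run A \code{"pa_run"}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters(run$clusters, file.path(dir, "pa"))
  write_profile(run$mono_profile, file.path(dir, "profile_mono.tsv"))
  write_profile(run$di_profile, file.path(dir, "profile_di.tsv"))
  utils::write.table(run$scan$counts, file.path(dir, "hexamer_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$usage, file.path(dir, "pas_usage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$pascalls, file.path(dir, "pas_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$assignments, file.path(dir, "feature_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$apa$per_gene, file.path(dir, "gene_apa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$chromosome_summary,
                     file.path(dir, "chromosome_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$report$table1, file.path(dir, "report_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_lines <- c(
    sprintf("total_pa_clusters\t%d", run$report$total_pa_clusters),
    sprintf("member_fraction_%s\t%.6f", names(run$report$member_fractions),
            run$report$member_fractions),
    sprintf("apa_fraction\t%.6f", run$report$apa_fraction),
    sprintf("genome_md5\t%s", run$genome_md5))
  writeLines(summary_lines, file.path(dir, "report_summary.txt"))
  invisible(dir)
}

#' Validate a synthetic run against its truth tables
#'
#' Measures cluster-position recall and precision (exact and within a
#' tolerance), the PAS-class confusion matrix against the planted hexamers,
#' feature-category accuracy, and the internal-priming decoy removal rate
#' (overall and among decoys whose downstream window genuinely meets the
#' window rule).
#'
#' @param run A \code{"pa_run"} produced from \code{sim}.
#' @param sim The simulation the run was executed on.
#' @param tolerance Matching tolerance in nt (default 20).
#' @return List of recovery metrics.
#' @export
validate_against_truth <- function(run, sim, tolerance = 20L) {
  if (!identical(run$genome_md5, .genome_md5(sim$genome)))
    stop("run/truth mismatch: the run was not produced on this genome ",
         "(md5 differs)")
  truth <- sim$sites
  cl <- run$clusters

  key <- function(chrom, strand) paste(chrom, strand)
  # index of (and distance to) the nearest ref position on the same
  # chromosome and strand, grouped + findInterval so large runs stay fast
  nearest <- function(q_pos, q_key, ref_pos, ref_key) {
    idx <- rep(NA_integer_, length(q_pos))
    dist <- rep(Inf, length(q_pos))
    refs <- split(seq_along(ref_pos), ref_key)
    qs <- split(seq_along(q_pos), q_key)
    for (k in names(qs)) {
      r <- refs[[k]]
      if (is.null(r)) next
      r <- r[order(ref_pos[r])]
      rp <- ref_pos[r]
      qi <- qs[[k]]
      iv <- findInterval(q_pos[qi], rp)
      lo <- pmax(iv, 1L); hi <- pmin(iv + 1L, length(rp))
      use_lo <- abs(q_pos[qi] - rp[lo]) <= abs(q_pos[qi] - rp[hi])
      pickd <- ifelse(use_lo, lo, hi)
      idx[qi] <- r[pickd]
      dist[qi] <- abs(q_pos[qi] - rp[pickd])
    }
    list(idx = idx, dist = dist)
  }
  tk <- key(truth$chrom, truth$strand)
  ck <- key(cl$chrom, cl$strand)
  to_clus <- nearest(truth$cleavage_position, tk,
                     cl$representative_position, ck)
  to_truth <- nearest(cl$representative_position, ck,
                      truth$cleavage_position, tk)
  recall_exact <- mean(to_clus$dist == 0)
  recall_tol <- mean(to_clus$dist <= tolerance)
  precision_exact <- mean(to_truth$dist == 0)
  precision_tol <- mean(to_truth$dist <= tolerance)

  # PAS confusion: clusters matched to the nearest truth site within tolerance
  matched <- ifelse(to_truth$dist <= tolerance, to_truth$idx, NA_integer_)
  ok <- !is.na(matched)
  planted <- truth$planted_hexamer[matched[ok]]
  assigned <- run$pascalls$pas[ok]
  lv <- c(pas_hexamers(), "none")
  confusion <- table(planted = factor(planted, levels = lv),
                     assigned = factor(assigned, levels = lv))
  pas_accuracy <- mean(planted == assigned)

  feat_truth <- truth$feature_category[matched[ok]]
  feat_assigned <- run$assignments$category[ok]
  feature_accuracy <- mean(feat_truth == feat_assigned)

  # decoy removal: events of decoy reads discarded by the priming filter
  decoy_removal <- NA_real_
  decoy_removal_qualifying <- NA_real_
  if (!is.null(sim$read_truth) && any(sim$read_truth$decoy)) {
    ev <- run$events
    is_decoy <- sim$read_truth$decoy[match(ev$read_id,
                                           sim$read_truth$read_id)]
    dec <- ev[is_decoy %in% TRUE, , drop = FALSE]
    if (nrow(dec)) {
      decoy_removal <- mean(!dec$keep)
      qual <- internal_priming_filter(
        dec[, c("chrom", "strand", "position", "read_id", "source_tag")],
        sim$genome, filter_config(mode = "window"))
      if (any(!qual$keep))
        decoy_removal_qualifying <- mean(!dec$keep[!qual$keep])
    }
  }
  list(n_truth_sites = nrow(truth), n_clusters = nrow(cl),
       recall_exact = recall_exact, recall_tol = recall_tol,
       precision_exact = precision_exact, precision_tol = precision_tol,
       pas_confusion = confusion, pas_accuracy = pas_accuracy,
       feature_accuracy = feature_accuracy,
       decoy_removal = decoy_removal,
       decoy_removal_qualifying = decoy_removal_qualifying,
       tolerance = tolerance)
}
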