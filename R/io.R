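## File-format plumbing: FASTA/FASTQ/GFF3/SAM writers for the simulator and
## the SAM/BAM reader used by site calling. Reading of standard formats goes
## through Biostrings / Rsamtools / GenomicAlignments / rtracklayer; the only
## writer implemented here is the (full-match-CIGAR) SAM formatter for
## simulated alignments.

#' Gene models of a simulation as a GFF3-ready GRanges
#'
#' @param sim Simulation list (from \code{\link{simulate_genome}} or later).
#' @return A \code{GRanges} with gene/mRNA/exon/CDS/UTR rows and ID/Parent
#'   attributes, 1-based closed coordinates.
#' @export
annotation_granges <- function(sim) {
  genes <- sim$genes
  feats <- sim$features
  mk <- function(chrom, start0, end0, strand, type, ID, Parent) {
    Parent <- rep_len(Parent, length(chrom))
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0 + 1L),
      strand = strand, type = type, ID = ID,
      Parent = IRanges::CharacterList(
        lapply(Parent, function(p) if (is.na(p)) character(0) else p)))
  }
  g <- mk(genes$chrom, genes$start, genes$end, genes$strand, "gene",
          genes$gene_id, NA_character_)
  tx_id <- paste0(genes$gene_id, ".t1")
  t <- mk(genes$chrom, genes$start, genes$end, genes$strand, "mRNA",
          tx_id, genes$gene_id)
  f <- feats[feats$type != "intron", ]
  fr <- mk(f$chrom, f$gstart, f$gend, f$strand, f$type,
           NA_character_, paste0(f$gene_id, ".t1"))
  gr <- c(g, t, fr)
  S4Vectors::mcols(gr)$phase <- ifelse(S4Vectors::mcols(gr)$type == "CDS",
                                       0L, NA_integer_)
  S4Vectors::mcols(gr)$source <- "pasite"
  names(gr) <- NULL
  gr
}

#' Write all simulation artefacts to a directory
#'
#' Writes \code{genome.fa}, \code{annotation.gff3}, \code{reads.fastq},
#' \code{alignments.sam}, \code{site_truth.tsv}, \code{read_truth.tsv} and
#' \code{config.txt}. Outputs are byte-identical across runs with the same
#' configuration (including seed).
#'
#' @param sim Full simulation (from \code{\link{simulate_pa_dataset}}).
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  rtracklayer::export(annotation_granges(sim),
                      file.path(dir, "annotation.gff3"), format = "gff3")
  if (!is.null(sim$reads)) {
    rs <- Biostrings::DNAStringSet(sim$reads$sequence)
    names(rs) <- sim$reads$read_id
    Biostrings::writeXStringSet(
      rs, file.path(dir, "reads.fastq"), format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(rs))))
    write_sam(sim$alignments, sim$genome, file.path(dir, "alignments.sam"))
    utils::write.table(sim$read_truth, file.path(dir, "read_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$sites))
    utils::write.table(sim$sites, file.path(dir, "site_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_sim_config(sim$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write simulated alignments as SAM
#'
#' Plain-text SAM with full-match CIGARs; coordinates follow the SAM
#' specification (1-based, leftmost).
#'
#' @param alignments Data frame with read_id, chrom, strand, start, end
#'   (0-based closed), seq (forward-strand sequence).
#' @param genome Named character vector (or \code{DNAStringSet}) of
#'   chromosome sequences, for the header.
#' @param path Output path.
#' @export
write_sam <- function(alignments, genome, path) {
  lens <- if (is.character(genome)) nchar(genome) else Biostrings::width(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  a <- alignments
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 a$read_id, ifelse(a$strand == "+", 0L, 16L), a$chrom,
                 a$start + 1L, a$end - a$start + 1L, a$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted with \code{Rsamtools::asBam}; records are returned
#' as a \code{GAlignments} (with read names). Secondary, supplementary and
#' unmapped records are dropped; a mapping-quality floor excludes
#' multi-mapping reads.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Mapping-quality floor (default 1).
#' @return \code{GAlignments} with a \code{source_tag}-free minimal schema.
#' @export
read_alignment_file <- function(path, min_mapq = 1L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq,
                                   what = "mapq")
  GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  cfg <- lapply(vals, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(cfg) <- keys
  # restore names of the named probability vectors
  if (!is.null(cfg$hexamer_usage))
    names(cfg$hexamer_usage) <- c(pas_hexamers(), "none")
  if (!is.null(cfg$sites_per_gene_dist))
    names(cfg$sites_per_gene_dist) <- c("1", "2", "3", "4", "5", ">5")
  if (!is.null(cfg$feature_mix))
    names(cfg$feature_mix) <- c("three_prime_utr", "intron", "exon",
                                "five_prime_utr")
  do.call(sim_config, cfg)
}

#' Write / read a simulation configuration as flat key=value text
#'
#' @param config A \code{\link{sim_config}}.
#' @param path File path.
#' @return \code{path} (write) or a \code{sim_config} (read).
#' @export
write_sim_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(format(v, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = ","), character(1))
  writeLines(sprintf("%s = %s", names(config), vals), path)
  invisible(path)
}
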