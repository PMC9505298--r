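## Site calling: per-read cleavage events from alignments of tail-trimmed
## sense reads, internal-priming artifact removal, and single-linkage
## clustering of events into pA sites.

# normalise a genome argument (DNAStringSet or named character) to strings
.genome_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    out
  } else genome
}

#' Call per-read cleavage events from alignments
#'
#' The cleavage base is the last transcribed (tail-adjacent) base of the
#' aligned sense read: for a read aligned to the + strand the reference
#' coordinate of the alignment's last aligned base; on the - strand the
#' alignment's leftmost reference base. Records whose 3' read end is soft- or
#' hard-clipped are rejected with reason \code{"clipped-end"}, since the
#' cleavage base is then not anchored to the reference.
#'
#' @param aln A \code{GAlignments} (e.g. from
#'   \code{\link{read_alignment_file}}) or a data frame with read_id, chrom,
#'   strand, start, end (0-based closed reference coordinates).
#' @param source_tag Source label, recycled (ignored if \code{aln} has one).
#' @return List with \code{events} (chrom, strand, position 0-based,
#'   read_id, source_tag) and \code{rejected} (read_id, reason).
#' @export
call_cleavage_events <- function(aln, source_tag = "long_read") {
  if (methods::is(aln, "GAlignments")) {
    cig <- GenomicAlignments::cigar(aln)
    strand <- as.character(GenomicAlignments::strand(aln))
    last_op <- sub(".*[0-9]+([MIDNSHP=X])$", "\\1", cig)
    first_op <- sub("^[0-9]+([MIDNSHP=X]).*", "\\1", cig)
    # read 3' terminus sits at the right of the alignment on +, left on -
    clipped <- ifelse(strand == "+", last_op %in% c("S", "H"),
                      first_op %in% c("S", "H"))
    df <- data.frame(
      read_id = if (is.null(names(aln))) as.character(seq_along(aln))
                else names(aln),
      chrom = as.character(GenomicAlignments::seqnames(aln)),
      strand = strand,
      start = GenomicAlignments::start(aln) - 1L,
      end = GenomicAlignments::end(aln) - 1L,
      stringsAsFactors = FALSE)
    df$source_tag <- rep_len(source_tag, nrow(df))
  } else {
    df <- aln
    if (is.null(df$source_tag)) df$source_tag <- rep_len(source_tag, nrow(df))
    clipped <- rep(FALSE, nrow(df))
  }
  rejected <- data.frame(read_id = df$read_id[clipped],
                         reason = rep("clipped-end", sum(clipped)),
                         stringsAsFactors = FALSE)
  df <- df[!clipped, , drop = FALSE]
  events <- data.frame(
    chrom = df$chrom, strand = df$strand,
    position = ifelse(df$strand == "+", df$end, df$start),
    read_id = df$read_id, source_tag = df$source_tag,
    stringsAsFactors = FALSE)
  list(events = events, rejected = rejected)
}

#' Restore a single templated A at the cleavage end
#'
#' Pure-A tail trimming cannot tell a tail adenosine from a genomic A
#' adjacent to the cleavage base, so alignments of trimmed reads stop one
#' base short wherever the cleavage base is the A of the canonical CA
#' dinucleotide. This step extends each event by exactly one base in the
#' transcript direction iff exactly one genomic sense A follows the
#' alignment end. Longer genomic A tracts are never restored, which keeps
#' the internal-priming signature (A-rich downstream window) intact.
#'
#' @param events Event data frame from \code{\link{call_cleavage_events}}.
#' @param genome Genome (named character vector or \code{DNAStringSet}).
#' @return Events with adjusted \code{position}.
#' @export
restore_templated_a <- function(events, genome) {
  genome <- .genome_strings(genome)
  if (nrow(events) == 0L) return(events)
  p <- events$position
  plus <- events$strand == "+"
  g <- genome[events$chrom]
  n1 <- ifelse(plus, substring(g, p + 2L, p + 2L), substring(g, p, p))
  n2 <- ifelse(plus, substring(g, p + 3L, p + 3L),
               substring(g, p - 1L, p - 1L))
  restore <- ifelse(plus, n1 == "A" & n2 != "A", n1 == "T" & n2 != "T")
  events$position <- p + ifelse(restore, ifelse(plus, 1L, -1L), 0L)
  events
}

#' Internal-priming filter configuration
#'
#' Two published rules are supported: the window rule (>= \code{min_at} A in
#' the \code{window_len} bases immediately downstream of the cleavage base)
#' and the run rule (a run of >= \code{min_run} consecutive A anywhere in
#' that window). A is counted on the transcript sense strand (equivalently T
#' on the reference for - strand events). Mode \code{"either"} (default)
#' discards an event if either rule fires.
#'
#' @param window_len Downstream window length, nt (default 10).
#' @param min_at Window-rule threshold (default 9).
#' @param min_run Run-rule threshold (default 8).
#' @param mode \code{"window"}, \code{"run"} or \code{"either"}.
#' @return List of class \code{"filter_config"}.
#' @export
filter_config <- function(window_len = 10L, min_at = 9L, min_run = 8L,
                          mode = c("either", "window", "run")) {
  mode <- match.arg(mode)
  stopifnot(min_at <= window_len, min_run >= 1L)
  structure(list(window_len = window_len, min_at = min_at,
                 min_run = min_run, mode = mode), class = "filter_config")
}

#' Remove internal-priming artifacts
#'
#' Oligo(dT) priming on genomic A-runs creates apparent cleavage sites whose
#' downstream genomic sequence is A-rich. Events are kept or discarded by
#' inspecting the sense-strand genomic bases at +1..+window_len downstream of
#' the cleavage base (truncated at contig edges and evaluated as-is).
#'
#' @param events Event data frame (chrom, strand, position).
#' @param genome Genome (named character vector or \code{DNAStringSet}).
#' @param config A \code{\link{filter_config}}.
#' @return \code{events} with added logical \code{keep} and character
#'   \code{filter_reason} (\code{NA} for kept events).
#' @export
internal_priming_filter <- function(events, genome, config = filter_config()) {
  genome <- .genome_strings(genome)
  if (nrow(events) == 0L) {
    events$keep <- logical(0)
    events$filter_reason <- character(0)
    return(events)
  }
  missing_chrom <- setdiff(unique(events$chrom), names(genome))
  if (length(missing_chrom))
    stop("contig(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  p <- events$position
  plus <- events$strand == "+"
  g <- genome[events$chrom]
  glen <- nchar(genome)[events$chrom] # lengths once per chrom, then lookup
  w <- ifelse(plus,
              substring(g, pmin(p + 2L, glen + 1L),
                        pmin(p + 1L + config$window_len, glen)),
              substring(g, pmax(p - config$window_len + 1L, 1L),
                        pmax(p, 0L)))
  base <- ifelse(plus, "A", "T")  # sense A is reference T on the - strand
  n_at <- ifelse(plus, .count_char(w, "A"), .count_char(w, "T"))
  has_run <- grepl(sprintf("A{%d}", config$min_run), w) & plus |
             grepl(sprintf("T{%d}", config$min_run), w) & !plus
  window_hit <- n_at >= config$min_at
  run_hit <- has_run
  discard <- switch(config$mode,
                    window = window_hit,
                    run = run_hit,
                    either = window_hit | run_hit)
  events$keep <- !discard
  events$filter_reason <- ifelse(discard,
                                 ifelse(window_hit, "a-rich-window", "a-run"),
                                 NA_character_)
  events
}

#' Cluster cleavage events into pA sites
#'
#' Single-linkage merging per (chrom, strand[, source]): adjacent distinct
#' event positions separated by <= \code{merge_distance} chain into one
#' cluster. The representative position is the member with maximal read
#' support; ties go to the 5'-most member (smallest coordinate on +, largest
#' on -). Output order is deterministic (chrom, strand, representative).
#'
#' @param events Event data frame (chrom, strand, position, optionally
#'   source_tag). Typically only events with \code{keep == TRUE}.
#' @param merge_distance Maximal gap merged, nt (default 20).
#' @param merge_sources If \code{FALSE} (default) sources are clustered
#'   separately, mirroring the additive per-source totals of the reference
#'   study; \code{TRUE} pools events across sources first.
#' @return Data frame of clusters: cluster_id, chrom, strand, source_tag,
#'   representative_position, n_members, total_support, start, end, and
#'   list columns member_positions / support_per_member.
#' @export
cluster_events <- function(events, merge_distance = 20L,
                           merge_sources = FALSE) {
  cols <- c("chrom", "strand", "position")
  if (nrow(events) == 0L)
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      strand = character(0), source_tag = character(0),
                      representative_position = integer(0),
                      n_members = integer(0), total_support = integer(0),
                      start = integer(0), end = integer(0)))
  if (is.null(events$source_tag) || merge_sources)
    events$source_tag <- "all"
  if (!is.null(events$keep)) events <- events[events$keep, , drop = FALSE]
  grp <- interaction(events$chrom, events$strand, events$source_tag,
                     drop = TRUE)
  pieces <- lapply(split(events[, c(cols, "source_tag")], grp), function(d) {
    tab <- table(d$position)
    pos <- as.integer(names(tab))
    sup <- as.integer(tab)
    o <- order(pos)
    pos <- pos[o]; sup <- sup[o]
    cl <- cumsum(c(1L, as.integer(diff(pos) > merge_distance)))
    res <- lapply(split(seq_along(pos), cl), function(ix) {
      m <- pos[ix]; s <- sup[ix]
      best <- which(s == max(s))
      rep_pos <- if (d$strand[1] == "+") m[best[1]] else m[best[length(best)]]
      list(m = m, s = s, rep = rep_pos)
    })
    data.frame(chrom = d$chrom[1], strand = d$strand[1],
               source_tag = d$source_tag[1],
               representative_position = vapply(res, `[[`, integer(1), "rep"),
               n_members = vapply(res, function(r) length(r$m), integer(1)),
               total_support = vapply(res, function(r) sum(r$s), integer(1)),
               start = vapply(res, function(r) r$m[1], integer(1)),
               end = vapply(res, function(r) r$m[length(r$m)], integer(1)),
               member_positions = I(lapply(res, `[[`, "m")),
               support_per_member = I(lapply(res, `[[`, "s")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$strand, out$representative_position,
                   out$source_tag), , drop = FALSE]
  out$cluster_id <- sprintf("pa%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", setdiff(names(out), "cluster_id"))]
}

#' Summarise pA clusters
#'
#' Reports per-source cluster counts (totalled additively) and the fraction
#' of clusters with one, two, or three-and-more member cleavage positions.
#'
#' @param clusters Output of \code{\link{cluster_events}}.
#' @return List with \code{per_source} (source_tag, n_clusters; plus a total
#'   row) and \code{member_fractions} (named numeric: one, two, several).
#' @export
summarize_sites <- function(clusters) {
  per_source <- as.data.frame(table(source_tag = clusters$source_tag),
                              stringsAsFactors = FALSE)
  names(per_source)[2] <- "n_clusters"
  per_source <- rbind(per_source,
                      data.frame(source_tag = "total",
                                 n_clusters = nrow(clusters)))
  mf <- c(one = mean(clusters$n_members == 1L),
          two = mean(clusters$n_members == 2L),
          several = mean(clusters$n_members >= 3L))
  list(per_source = per_source, member_fractions = mf)
}

#' Naive unique exact-match aligner (fixture scale)
#'
#' Places each sense read by exact full-length match against the genome
#' (forward hit = + strand; reverse-complement hit = - strand). Reads with
#' anything other than exactly one hit are dropped. Intended only for small
#' synthetic fixtures; real data should be aligned externally and ingested
#' as SAM/BAM.
#'
#' @param sense_seqs Character vector of sense read sequences.
#' @param genome Genome (named character vector or \code{DNAStringSet}).
#' @param read_id Read identifiers.
#' @param source_tag Source label, recycled.
#' @return Alignment data frame (read_id, chrom, strand, start, end 0-based
#'   closed, source_tag); unplaced reads are absent.
#' @export
align_reads_naive <- function(sense_seqs, genome, read_id = NULL,
                              source_tag = "long_read") {
  genome <- .genome_strings(genome)
  if (is.null(read_id)) read_id <- as.character(seq_along(sense_seqs))
  subjects <- Biostrings::DNAStringSet(genome)
  source_tag <- rep_len(source_tag, length(sense_seqs))
  rows <- vector("list", length(sense_seqs))
  for (i in seq_along(sense_seqs)) {
    hits <- list()
    for (ch in names(genome)) {
      for (st in c("+", "-")) {
        pat <- if (st == "+") sense_seqs[i] else .revcomp(sense_seqs[i])
        m <- Biostrings::matchPattern(pat, subjects[[ch]])
        if (length(m))
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = ch, strand = st,
            start = Biostrings::start(m) - 1L,
            end = Biostrings::end(m) - 1L, stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else NULL
    if (!is.null(hits) && nrow(hits) == 1L) {
      hits$read_id <- read_id[i]
      hits$source_tag <- source_tag[i]
      rows[[i]] <- hits
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      read_id = character(0), source_tag = character(0))
  out[, c("read_id", "chrom", "strand", "start", "end", "source_tag")]
}

#' Write clusters as BED6 plus a members TSV
#'
#' BED is 0-based half-open; the name column is the cluster_id and the score
#' the total read support.
#'
#' @param clusters Output of \code{\link{cluster_events}}.
#' @param out_prefix Output path prefix.
#' @return The two paths written, invisibly.
#' @export
write_clusters <- function(clusters, out_prefix) {
  bed <- paste0(out_prefix, ".clusters.bed")
  tsv <- paste0(out_prefix, ".members.tsv")
  flat <- paste0(out_prefix, ".clusters.tsv")
  utils::write.table(
    clusters[, c("cluster_id", "chrom", "strand", "representative_position",
                 "n_members", "total_support", "start", "end", "source_tag")],
    flat, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(clusters$chrom, clusters$start,
                       clusters$end + 1L, clusters$cluster_id,
                       clusters$total_support, clusters$strand)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  members <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i)
    data.frame(cluster_id = clusters$cluster_id[i],
               position = clusters$member_positions[[i]],
               support = clusters$support_per_member[[i]])))
  utils::write.table(members, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed, tsv, flat))
}

#' Read a flat clusters TSV back
#'
#' Round-trips the \code{.clusters.tsv} written by
#' \code{\link{write_clusters}} for downstream profiling/annotation.
#'
#' @param path Path to a clusters TSV.
#' @return Cluster data frame (without member list columns).
#' @export
read_clusters <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
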