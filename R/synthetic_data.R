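#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic 3' end
#' sequencing generator. The generator emulates the statistical structure the
#' downstream analysis assumes: an AT-rich genome (default GC 36.4%), gene
#' models with exon/intron/UTR structure, planted cleavage sites with local
#' read-level heterogeneity, PAS hexamers written at -30..-11 upstream of the
#' cleavage base according to a usage distribution, U-rich downstream
#' elements, poly(A)/poly(T) read tails of length >= 10, and internal-priming
#' decoy reads arising at genomic A-runs.
#'
#' Length parameters (\code{exon_len}, \code{intron_len}, \code{utr5_len},
#' \code{utr3_len}, \code{read_len}, \code{intergenic_len}) are inclusive
#' integer ranges \code{c(min, max)} sampled uniformly.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param gc_content Genome GC fraction in (0,1); bases are drawn i.i.d. with
#'   P(G)=P(C)=gc/2 and P(A)=P(T)=(1-gc)/2 outside planted elements.
#' @param n_chromosomes,chrom_length Number of chromosomes and their length
#'   (nt). Genes that do not fit raise a sizing error.
#' @param n_genes Total genes, distributed evenly across chromosomes.
#' @param exons_per_gene Range of exon counts per gene (min 2).
#' @param exon_len,intron_len,utr5_len,utr3_len Structure length ranges (nt).
#' @param sites_per_gene_dist Probability vector over site-count classes
#'   \code{c("1","2","3","4","5",">5")}; the ">5" class draws 6-8 sites.
#' @param hexamer_usage Probability vector over \code{c(pas_hexamers(),
#'   "none")}; defaults to the reference usage table
#'   (\code{\link{pas_usage_reference}}).
#' @param pas_offset_range Range of the planted hexamer's 5'-base offset
#'   relative to the cleavage base (default \code{c(-30, -11)}); must leave
#'   room for the whole hexamer upstream of the cleavage base.
#' @param feature_mix Probability vector over
#'   \code{c("three_prime_utr","intron","exon","five_prime_utr")} for
#'   non-distal sites (the distal site of every gene is in the 3'UTR).
#' @param dse_u_fraction Probability of U (T on the sense strand) per base in
#'   the downstream-sequence-element window.
#' @param dse_window Downstream window rewritten U-rich, relative to the
#'   cleavage base (default \code{c(3, 27)}).
#' @param cs_a_prob Probability that the planted cleavage base is A. When it
#'   is, the generator writes the canonical CA dinucleotide at -1..0 and keeps
#'   +1..+2 A-free so the cleavage base stays identifiable under pure-A tails.
#' @param site_heterogeneity Probability that a planted site shows cleavage
#'   heterogeneity at all; the remaining sites cleave at the planted base in
#'   every read. Default 0.65, echoing the observed share of pA clusters
#'   with a single cleavage position (~35%).
#' @param cs_jitter_sd Standard deviation (nt) of per-read cleavage jitter at
#'   heterogeneous sites (rounded Gaussian, truncated at +/-10). 0 means
#'   every read cleaves at the planted base.
#' @param tail_len_min,tail_len_lambda Tail length is
#'   \code{tail_len_min + Poisson(tail_len_lambda)}; minimum must be >= 10.
#'   \code{tail_len_lambda = 0} gives constant tails.
#' @param reads_per_site True reads generated per planted site.
#' @param decoy_fraction Fraction of emitted reads that are internal-priming
#'   decoys primed at genomic A-runs (>= 8 consecutive A on the sense strand).
#' @param error_rate Per-base substitution probability outside the tail.
#' @param read_len Range of templated (pre-tail) read lengths.
#' @param min_site_spacing Minimum distance (nt) between planted sites of one
#'   gene, so that read jitter cannot merge neighbouring sites.
#' @param est_fraction Fraction of reads tagged as source "EST" (the rest are
#'   "long_read").
#' @param intergenic_len Range of intergenic spacer lengths.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       gc_content = 0.364,
                       n_chromosomes = 4L,
                       chrom_length = 200000L,
                       n_genes = 200L,
                       exons_per_gene = c(3L, 3L),
                       exon_len = c(150L, 300L),
                       intron_len = c(100L, 400L),
                       utr5_len = c(150L, 300L),
                       utr3_len = c(450L, 800L),
                       sites_per_gene_dist = c("1" = 0.2959, "2" = 0.2941,
                                               "3" = 0.17, "4" = 0.11,
                                               "5" = 0.07, ">5" = 0.06),
                       hexamer_usage = pas_usage_reference(),
                       pas_offset_range = c(-30L, -11L),
                       feature_mix = c(three_prime_utr = 0.6548,
                                       intron = 0.2486,
                                       exon = 0.0823,
                                       five_prime_utr = 0.0143),
                       dse_u_fraction = 0.45,
                       dse_window = c(3L, 27L),
                       cs_a_prob = 0.62,
                       site_heterogeneity = 0.65,
                       cs_jitter_sd = 1,
                       tail_len_min = 10L,
                       tail_len_lambda = 15,
                       reads_per_site = 5L,
                       decoy_fraction = 0.05,
                       error_rate = 0,
                       read_len = c(150L, 400L),
                       min_site_spacing = 60L,
                       est_fraction = 0,
                       intergenic_len = c(200L, 400L)) {
  cfg <- as.list(environment())
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  .stopifnot_prob(sites_per_gene_dist, "sites_per_gene_dist")
  .stopifnot_prob(feature_mix, "feature_mix")
  usage <- hexamer_usage
  if (is.null(names(usage)) ||
      !identical(sort(names(usage)), sort(c(pas_hexamers(), "none"))))
    stop("hexamer_usage must be named over c(pas_hexamers(), 'none')")
  .stopifnot_prob(usage, "hexamer_usage")
  cfg$hexamer_usage <- usage[c(pas_hexamers(), "none")]
  if (pas_offset_range[1] > pas_offset_range[2] || pas_offset_range[2] > -6L)
    stop("pas_offset_range must lie strictly upstream of the cleavage site ",
         "with room for a full hexamer (upper bound <= -6)")
  if (tail_len_min < 10L) stop("tail length support must be >= 10 nt")
  if (exons_per_gene[1] < 2L) stop("genes need at least 2 exons")
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("decoy_fraction must be in [0,1)")
  structure(cfg, class = "sim_config")
}

.runifint <- function(n, range) {
  if (range[1] == range[2]) rep.int(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

## ---------------------------------------------------------------------------
## simulate_genome: i.i.d. genome + gene model coordinates (nothing planted)
## ---------------------------------------------------------------------------

#' Simulate a genome and gene models
#'
#' Draws an i.i.d. genome at the configured GC content and lays out
#' strand-assigned, non-overlapping gene models (5'UTR / exons / introns /
#' CDS / 3'UTR) separated by intergenic spacers. No site-specific elements
#' are written at this stage; see \code{\link{plant_pa_sites}}.
#'
#' Coordinates are 0-based closed internally. Local ("l") coordinates run
#' 5' to 3' along the transcript sense strand, 0 at the gene 5' end.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome} (named character vector, one string per
#'   chromosome), \code{genes}, \code{features} (data frames) and
#'   \code{config}. Deterministic given \code{config$seed}.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome <- vapply(chroms, function(ch) {
    paste0(.draw_bases(config$chrom_length, config$gc_content), collapse = "")
  }, character(1))

  per_chrom <- tabulate(rep_len(seq_len(config$n_chromosomes), config$n_genes),
                        nbins = config$n_chromosomes)
  genes <- vector("list", config$n_genes)
  feats <- vector("list", config$n_genes)
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    pos <- 0L
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      nex <- .runifint(1L, config$exons_per_gene)
      exl <- .runifint(nex, config$exon_len)
      inl <- .runifint(nex - 1L, config$intron_len)
      u5 <- .runifint(1L, config$utr5_len)
      u3 <- .runifint(1L, config$utr3_len)
      # local layout: [u5][cds1] i1 [cds2] i2 ... [cds_k][u3]
      lex_len <- exl
      lex_len[1] <- lex_len[1] + u5
      lex_len[nex] <- lex_len[nex] + u3
      lstart <- integer(nex)
      cur <- 0L
      lfe <- list()
      for (e in seq_len(nex)) {
        lstart[e] <- cur
        lfe[[length(lfe) + 1L]] <-
          data.frame(type = "exon", lstart = cur, lend = cur + lex_len[e] - 1L)
        if (e < nex) {
          icur <- cur + lex_len[e]
          lfe[[length(lfe) + 1L]] <-
            data.frame(type = "intron", lstart = icur, lend = icur + inl[e] - 1L)
          cur <- icur + inl[e]
        } else cur <- cur + lex_len[e]
      }
      span <- cur
      lfe[[length(lfe) + 1L]] <-
        data.frame(type = "five_prime_UTR", lstart = 0L, lend = u5 - 1L)
      lfe[[length(lfe) + 1L]] <-
        data.frame(type = "three_prime_UTR", lstart = span - u3, lend = span - 1L)
      # CDS = exon minus the UTR parts
      cds <- data.frame(type = "CDS",
                        lstart = lstart + c(u5, integer(nex - 1L)),
                        lend = lstart + lex_len - 1L - c(integer(nex - 1L), u3))
      lf <- rbind(do.call(rbind, lfe), cds)

      spacer <- .runifint(1L, config$intergenic_len)
      g0 <- pos + spacer
      pos <- g0 + span
      if (pos > config$chrom_length)
        stop("genes do not fit in chromosome ", chroms[ci],
             ": need > ", pos, " nt but chrom_length = ", config$chrom_length,
             " (reduce n_genes or raise chrom_length)")
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("g%05d", gi)
      genes[[gi]] <- data.frame(
        gene_id = gene_id, chrom = chroms[ci], strand = strand,
        start = g0, end = g0 + span - 1L, span = span,
        stringsAsFactors = FALSE)
      lf$gene_id <- gene_id
      feats[[gi]] <- lf
    }
  }
  genes <- do.call(rbind, genes)
  features <- do.call(rbind, feats)
  features <- merge(features, genes[, c("gene_id", "chrom", "strand", "start",
                                        "span")], by = "gene_id")
  # local -> genomic (0-based closed)
  plus <- features$strand == "+"
  features$gstart <- ifelse(plus, features$start + features$lstart,
                            features$start + features$span - 1L - features$lend)
  features$gend <- ifelse(plus, features$start + features$lend,
                          features$start + features$span - 1L - features$lstart)
  features <- features[, c("gene_id", "chrom", "strand", "type",
                           "lstart", "lend", "gstart", "gend")]
  features <- features[order(features$gene_id, features$type, features$lstart), ]
  rownames(features) <- NULL
  list(genome = genome, genes = genes, features = features, config = config)
}

## ---------------------------------------------------------------------------
## plant_pa_sites: edit the genome around drawn cleavage sites
## ---------------------------------------------------------------------------

# extract local sense window [a, b] (local coords, may exceed the gene span)
# from a chromosome string, for a gene at genomic start g0 with given span
.local_extract <- function(chromseq, g0, span, strand, a, b) {
  if (strand == "+") {
    substr(chromseq, g0 + a + 1L, g0 + b + 1L)
  } else {
    .revcomp(substr(chromseq, g0 + span - b, g0 + span - a))
  }
}

# turn local sense edits (positions `lpos`, characters `chars`) into genomic
# (index, char) pairs; index is 1-based into the chromosome string
.local_edit_idx <- function(g0, span, strand, lpos) {
  if (strand == "+") g0 + lpos + 1L else g0 + span - lpos
}
.local_edit_chr <- function(strand, chars) {
  if (strand == "+") chars else chartr("ACGTN", "TGCAN", chars)
}

# sample `m` positions from [lo, hi] with pairwise distance >= gap (sorted)
.spaced_sample <- function(m, lo, hi, gap) {
  L <- hi - lo + 1L - (m - 1L) * gap
  if (L < m) return(NULL)
  sort(sample.int(L, m)) - 1L + lo + (seq_len(m) - 1L) * gap
}

.draw_nonA <- function(n, gc) {
  sample(c("C", "G", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2))
}

#' Plant cleavage sites, PAS hexamers and downstream elements
#'
#' For every gene draws a site count from \code{sites_per_gene_dist} and
#' places the distal site in the 3'UTR and earlier sites per
#' \code{feature_mix}, then edits the genome on the transcript sense strand
#' around each site: the 40-nt upstream window is scrubbed of accidental PAS
#' hexamers and the drawn hexamer (if not "none") written at a uniform offset
#' in \code{pas_offset_range}; the downstream window is rewritten U-rich; the
#' cleavage base is set to A with probability \code{cs_a_prob} (with a C at
#' -1, the canonical CA) and the two bases downstream are kept A-free so the
#' cleavage coordinate remains identifiable under pure-A tails. The
#' 10-nt downstream window of every true site is guaranteed to pass the
#' internal-priming filter, so filter sensitivity is measurable on decoys
#' alone.
#'
#' @param sim Output of \code{\link{simulate_genome}}.
#' @param max_retries Bounded retries for hexamer scrubbing/placement.
#' @return \code{sim} with an edited \code{genome} plus \code{sites}, the
#'   per-site truth table (site_id, gene_id, chrom, strand,
#'   cleavage_position (0-based, last transcribed base), planted_hexamer
#'   (RNA alphabet or "none"), hexamer_offset, feature_category, is_distal).
#' @export
plant_pa_sites <- function(sim, max_retries = 60L) {
  config <- sim$config
  set.seed(config$seed + 1L)
  gc <- config$gc_content
  motifs <- pas_hexamers("DNA")
  motif_alt <- paste0("(?=(", paste(motifs, collapse = "|"), "))")
  genes <- sim$genes
  feats <- sim$features
  genome_vec <- lapply(sim$genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  classes <- names(config$sites_per_gene_dist)
  ksamp <- sample(classes, nrow(genes), replace = TRUE,
                  prob = config$sites_per_gene_dist)
  nsites <- ifelse(ksamp == ">5", sample(6:8, nrow(genes), replace = TRUE),
                   suppressWarnings(as.integer(ksamp)))

  feats_by_gene <- split(feats, feats$gene_id)
  out <- vector("list", nrow(genes))
  site_counter <- 0L

  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    lf <- feats_by_gene[[g$gene_id]]
    k <- nsites[gi]
    u3 <- lf[lf$type == "three_prime_UTR", c("lstart", "lend")]
    u5 <- lf[lf$type == "five_prime_UTR", c("lstart", "lend")]
    introns <- lf[lf$type == "intron", c("lstart", "lend")]
    cds <- lf[lf$type == "CDS", c("lstart", "lend")]
    spacing <- config$min_site_spacing
    lo3 <- max(u3$lstart, 45L)
    hi3 <- min(u3$lend, g$span - 31L)

    placed <- NULL
    for (attempt in seq_len(max_retries)) {
      cats <- c(if (k > 1L) sample(names(config$feature_mix), k - 1L,
                                   replace = TRUE, prob = config$feature_mix),
                "three_prime_utr")
      n3 <- sum(cats == "three_prime_utr")
      p3 <- .spaced_sample(n3, lo3, hi3, spacing)
      if (is.null(p3)) { k <- max(1L, k - 1L); next }
      pos <- p3
      cat_out <- rep("three_prime_utr", n3)
      ok <- TRUE
      for (cat in c("five_prime_utr", "intron", "exon")) {
        m <- sum(cats == cat)
        if (m == 0L) next
        iv <- switch(cat, five_prime_utr = u5, intron = introns, exon = cds)
        # clip intervals to legal site range, weight by length
        iv$lstart <- pmax(iv$lstart, 45L)
        iv$lend <- pmin(iv$lend, g$span - 31L)
        iv <- iv[iv$lend >= iv$lstart, , drop = FALSE]
        if (nrow(iv) == 0L) { ok <- FALSE; break }
        w <- iv$lend - iv$lstart + 1L
        pick <- sample.int(nrow(iv), m, replace = TRUE, prob = w)
        cand <- vapply(pick, function(j)
          .runifint(1L, c(iv$lstart[j], iv$lend[j])), integer(1))
        pos <- c(pos, cand)
        cat_out <- c(cat_out, rep(cat, m))
      }
      if (!ok) next
      o <- order(pos)
      pos <- pos[o]; cat_out <- cat_out[o]
      if (k > 1L && any(diff(pos) < spacing)) next
      placed <- data.frame(lpos = pos, category = cat_out,
                           stringsAsFactors = FALSE)
      break
    }
    if (is.null(placed))
      stop("site placement failed after ", max_retries, " retries for gene ",
           g$gene_id)
    placed$is_distal <- seq_len(nrow(placed)) == nrow(placed)

    hx <- sample(names(config$hexamer_usage), nrow(placed), replace = TRUE,
                 prob = config$hexamer_usage)
    offs <- .runifint(nrow(placed), config$pas_offset_range)
    offs[hx == "none"] <- NA_integer_

    ch <- g$chrom
    for (si in seq_len(nrow(placed))) {
      s <- placed$lpos[si]
      # -- upstream window: scrub + write hexamer ---------------------------
      win_ok <- FALSE
      planted_at <- if (is.na(offs[si])) NA_integer_ else offs[si] + 41L # 1-based in window
      for (it in seq_len(max_retries)) {
        w <- paste0(.draw_bases(40L, gc), collapse = "")
        if (!is.na(planted_at))
          substr(w, planted_at, planted_at + 5L) <- .rna2dna(hx[si])
        hits <- .find_all(w, paste(motifs, collapse = "|"))[[1]]
        if (length(setdiff(hits, planted_at)) == 0L) { win_ok <- TRUE; break }
      }
      if (!win_ok)
        stop("hexamer placement failed after ", max_retries,
             " retries for gene ", g$gene_id)
      wchars <- strsplit(w, "", fixed = TRUE)[[1]]
      lpos_edit <- (s - 40L):(s - 1L)
      chars_edit <- wchars
      # -- cleavage base and its immediate context --------------------------
      if (runif(1) < config$cs_a_prob) {
        chars_edit[40L] <- "C" # canonical CA at -1..0
        cs_edit_pos <- s
        cs_edit_chr <- "A"
      } else {
        cs_edit_pos <- s
        cs_edit_chr <- .draw_nonA(1L, gc)
      }
      lpos_edit <- c(lpos_edit, cs_edit_pos, s + 1L, s + 2L)
      chars_edit <- c(chars_edit, cs_edit_chr, .draw_nonA(2L, gc))
      # -- downstream element: U-rich, must pass the priming filter ---------
      dw <- config$dse_window
      ndse <- dw[2] - dw[1] + 1L
      repeat {
        isT <- runif(ndse) < config$dse_u_fraction
        dse <- ifelse(isT, "T",
                      sample(c("A", "C", "G"), ndse, replace = TRUE,
                             prob = c((1 - gc) / 2, gc / 2, gc / 2)))
        # filter window is +1..+10; +1,+2 are A-free, so only a full A-run
        # over +3..+10 could trip the run rule
        head10 <- dse[seq_len(max(0L, 10L - dw[1] + 1L))]
        if (!all(head10 == "A")) break
      }
      lpos_edit <- c(lpos_edit, dw[1]:dw[2] + s)
      chars_edit <- c(chars_edit, dse)
      idx <- .local_edit_idx(g$start, g$span, g$strand, lpos_edit)
      genome_vec[[ch]][idx] <- .local_edit_chr(g$strand, chars_edit)

      site_counter <- site_counter + 1L
      gpos <- if (g$strand == "+") g$start + s else g$start + g$span - 1L - s
      out[[site_counter]] <- data.frame(
        site_id = sprintf("s%06d", site_counter),
        gene_id = g$gene_id, chrom = ch, strand = g$strand,
        cleavage_position = gpos,
        planted_hexamer = hx[si],
        hexamer_offset = offs[si],
        feature_category = placed$category[si],
        is_distal = placed$is_distal[si],
        stringsAsFactors = FALSE)
    }
  }
  sim$genome <- vapply(genome_vec, paste0, character(1), collapse = "")
  sim$sites <- do.call(rbind, out[seq_len(site_counter)])
  rownames(sim$sites) <- NULL
  sim$sites$heterogeneous <- stats::runif(nrow(sim$sites)) <
    config$site_heterogeneity
  sim
}

## ---------------------------------------------------------------------------
## simulate_reads
## ---------------------------------------------------------------------------

# maximal A-run (sense) ending at 0-based position p; genome-side scan
.sense_a_run_end <- function(chromseq, p, strand, context = 60L) {
  if (strand == "+") {
    ctx <- substr(chromseq, pmax(1L, p - context + 2L), p + 1L)
    .terminal_run(ctx, "A", "3p")
  } else {
    ctx <- substr(chromseq, p + 1L, pmin(nchar(chromseq), p + context))
    .terminal_run(ctx, "T", "5p")
  }
}

# observable cleavage coordinate given a templated end: strip the terminal
# sense A-run the tail would absorb, then restore a single templated A
.observable_end <- function(chromseq, p, strand) {
  run <- .sense_a_run_end(chromseq, p, strand)
  if (strand == "+") {
    e <- p - run
    nxt1 <- substring(chromseq, e + 2L, e + 2L)
    nxt2 <- substring(chromseq, e + 3L, e + 3L)
    ifelse(nxt1 == "A" & nxt2 != "A", e + 1L, e)
  } else {
    e <- p + run
    nxt1 <- substring(chromseq, e, e)
    nxt2 <- substring(chromseq, e - 1L, e - 1L)
    ifelse(nxt1 == "T" & nxt2 != "T", e - 1L, e)
  }
}

#' Simulate poly(A)-evidence reads
#'
#' Emits one FASTQ-ready read set: per planted site, \code{reads_per_site}
#' reads whose templated portion is the genomic sense sequence ending at the
#' (jittered) cleavage position, plus a pure-A tail; additionally a
#' binomial number of internal-priming decoy reads ending at genomic A-runs
#' (>= 8 consecutive sense A). Half the reads are emitted
#' reverse-complemented so they begin with poly(T). Substitution errors are
#' applied to the templated portion at \code{error_rate}.
#'
#' The read-level truth table records, besides the physical templated end,
#' the \emph{observable} cleavage coordinate: pure-A tails absorb any
#' genomic A-run adjacent to the cleavage base, and the pipeline's convention
#' restores exactly one templated A (see the package vignette), so the two
#' coordinates differ where the templated end sits in a genomic A-run.
#'
#' Alignments of the tail-trimmed sense reads are returned alongside
#' (0-based closed reference coordinates) for consumption by the site-calling
#' stage; spans are truncated to the post-trim end, i.e. they carry no more
#' information than a real aligner would recover.
#'
#' @param sim Output of \code{\link{plant_pa_sites}}.
#' @return \code{sim} with \code{reads} (read_id, sequence, source_tag),
#'   \code{read_truth} and \code{alignments} data frames.
#' @export
simulate_reads <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 2L)
  sites <- sim$sites
  genome <- sim$genome
  gc <- config$gc_content

  n_true <- nrow(sites) * config$reads_per_site
  n_planned <- if (config$decoy_fraction > 0)
    as.integer(round(n_true / (1 - config$decoy_fraction))) else n_true
  n_decoy <- if (config$decoy_fraction > 0)
    stats::rbinom(1L, n_planned, config$decoy_fraction) else 0L

  ## -- true reads ------------------------------------------------------------
  idx <- rep(seq_len(nrow(sites)), each = config$reads_per_site)
  chrom <- sites$chrom[idx]
  strand <- sites$strand[idx]
  p <- sites$cleavage_position[idx]
  if (config$cs_jitter_sd > 0) {
    jit <- as.integer(round(stats::rnorm(n_true, 0, config$cs_jitter_sd)))
    jit <- pmax(pmin(jit, 10L), -10L)
    jit[!sites$heterogeneous[idx]] <- 0L # homogeneous sites never wobble
    p <- p + ifelse(strand == "+", jit, -jit) # jitter in transcript direction
  }
  site_id <- sites$site_id[idx]
  decoy <- rep(FALSE, n_true)

  ## -- decoy reads -----------------------------------------------------------
  if (n_decoy > 0L) {
    runs <- .find_sense_a_runs(genome, min_run = 8L,
                               exclude = sites, exclude_dist = 60L)
    if (nrow(runs) == 0L) {
      warning("no genomic A-run >= 8 nt available; decoys skipped")
      n_decoy <- 0L
    } else {
      pick <- sample.int(nrow(runs), n_decoy, replace = TRUE)
      chrom <- c(chrom, runs$chrom[pick])
      strand <- c(strand, runs$strand[pick])
      # templated portion runs through the whole A-run (primer anneals on it)
      p <- c(p, ifelse(runs$strand[pick] == "+", runs$end[pick],
                       runs$start[pick]))
      site_id <- c(site_id, rep(NA_character_, n_decoy))
      decoy <- c(decoy, rep(TRUE, n_decoy))
    }
  }

  n <- length(p)
  ord <- sample.int(n) # shuffle so read order carries no truth signal
  chrom <- chrom[ord]; strand <- strand[ord]; p <- p[ord]
  site_id <- site_id[ord]; decoy <- decoy[ord]

  read_id <- sprintf("r%07d", seq_len(n))
  L <- .runifint(n, config$read_len)
  tail_len <- config$tail_len_min +
    if (config$tail_len_lambda > 0) stats::rpois(n, config$tail_len_lambda)
    else 0L
  clen <- nchar(genome)[chrom]

  plus <- strand == "+"
  tstart <- ifelse(plus, pmax(0L, p - L + 1L), p)
  tend <- ifelse(plus, p, pmin(clen - 1L, p + L - 1L))
  templ <- substring(genome[chrom], tstart + 1L, tend + 1L)
  templ[!plus] <- .revcomp(templ[!plus])

  if (config$error_rate > 0) {
    nerr <- stats::rbinom(n, nchar(templ), config$error_rate)
    for (i in which(nerr > 0L)) {
      v <- strsplit(templ[i], "", fixed = TRUE)[[1]]
      at <- sample.int(length(v), nerr[i])
      v[at] <- vapply(v[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      templ[i] <- paste0(v, collapse = "")
    }
  }

  seqs <- paste0(templ, strrep("A", tail_len))
  flip <- stats::runif(n) < 0.5
  seqs[flip] <- .revcomp(seqs[flip])
  source_tag <- ifelse(stats::runif(n) < config$est_fraction, "EST", "long_read")

  ## -- observable ends and alignments of the trimmed sense reads ------------
  # trim from the read itself (errors may have created/destroyed terminal As),
  # then single-A restoration from the genome
  trim_run <- .terminal_run(templ, "A", "3p")
  e_trim <- ifelse(plus, tend - trim_run, tstart + trim_run)
  nxt1 <- ifelse(plus, substring(genome[chrom], e_trim + 2L, e_trim + 2L),
                 substring(genome[chrom], e_trim, e_trim))
  nxt2 <- ifelse(plus, substring(genome[chrom], e_trim + 3L, e_trim + 3L),
                 substring(genome[chrom], e_trim - 1L, e_trim - 1L))
  obs <- ifelse(plus,
                ifelse(nxt1 == "A" & nxt2 != "A", e_trim + 1L, e_trim),
                ifelse(nxt1 == "T" & nxt2 != "T", e_trim - 1L, e_trim))

  astart <- ifelse(plus, tstart, e_trim)
  aend <- ifelse(plus, e_trim, tend)
  aligned <- (aend - astart + 1L) >= 20L
  # forward-strand sequence of the trimmed read (not the reference: the read
  # may carry substitution errors)
  atempl <- substr(templ, 1L, nchar(templ) - trim_run)
  aseq <- ifelse(plus, atempl, NA_character_)
  if (any(!plus)) aseq[!plus] <- .revcomp(atempl[!plus])

  sim$reads <- data.frame(read_id = read_id, sequence = seqs,
                          source_tag = source_tag, stringsAsFactors = FALSE)
  sim$read_truth <- data.frame(
    read_id = read_id, site_id = site_id, decoy = decoy,
    chrom = chrom, strand = strand,
    templated_end = p, observable_end = obs, tail_length = tail_len,
    source_tag = source_tag, flipped = flip, aligned = aligned,
    stringsAsFactors = FALSE)
  sim$alignments <- data.frame(
    read_id = read_id[aligned], chrom = chrom[aligned],
    strand = strand[aligned], start = astart[aligned], end = aend[aligned],
    seq = aseq[aligned], source_tag = source_tag[aligned],
    stringsAsFactors = FALSE)
  sim
}

# sense-strand A-runs (A{n,} on + / T{n,} on -) away from planted sites
.find_sense_a_runs <- function(genome, min_run = 8L, exclude = NULL,
                               exclude_dist = 60L) {
  res <- list()
  for (ch in names(genome)) {
    for (st in c("+", "-")) {
      pat <- if (st == "+") sprintf("A{%d,}", min_run)
             else sprintf("T{%d,}", min_run)
      m <- gregexpr(pat, genome[[ch]])[[1]]
      if (m[1] == -1L) next
      st0 <- as.integer(m) - 1L
      en0 <- st0 + attr(m, "match.length") - 1L
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, strand = st, start = st0, end = en0,
        stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(res)) do.call(rbind, res)
          else data.frame(chrom = character(), strand = character(),
                          start = integer(), end = integer())
  if (!is.null(exclude) && nrow(runs) > 0L && nrow(exclude) > 0L) {
    keep <- vapply(seq_len(nrow(runs)), function(i) {
      s <- exclude[exclude$chrom == runs$chrom[i], "cleavage_position"]
      !length(s) || min(abs(s - runs$start[i]), abs(s - runs$end[i])) > exclude_dist
    }, logical(1))
    runs <- runs[keep, , drop = FALSE]
  }
  runs
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: \code{\link{simulate_genome}} then
#' \code{\link{plant_pa_sites}} then \code{\link{simulate_reads}}, optionally
#' writing all artefacts to disk (\code{\link{write_simulation}}).
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional output directory.
#' @return The full simulation list.
#' @export
simulate_pa_dataset <- function(config, dir = NULL) {
  sim <- simulate_reads(plant_pa_sites(simulate_genome(config)))
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}
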