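## Placement of pA clusters onto gene models: GFF3 loading, feature-category
## assignment with precedence, per-gene APA summaries and type classification,
## and per-chromosome site/gene ratios.
##
## Category semantics: "exon" means CDS-bearing exon sequence; the UTRs are
## reported separately so the four categories partition genic space.

#' Load gene models from GFF3
#'
#' Reads gene/mRNA/exon structure (CDS and UTR features optional). Missing
#' UTRs are inferred as exon minus CDS, split by side relative to the CDS in
#' transcript orientation; without a CDS no UTR is inferred. Intron ranges
#' are derived as gene span minus exons.
#'
#' @param gff Path to a GFF3 file, or a \code{GRanges} with type/ID/Parent
#'   columns (e.g. \code{\link{annotation_granges}} output).
#' @return List of class \code{"gene_models"}: \code{genes} (data frame:
#'   gene_id, chrom, strand, start, end; 0-based closed) and \code{features}
#'   (\code{GRanges}, 1-based, with gene_id and category in
#'   three_prime_utr / five_prime_utr / exon / intron).
#' @export
load_annotation <- function(gff) {
  if (is.character(gff)) {
    lines <- readLines(gff, warn = FALSE)
    if (!any(nzchar(lines) & !startsWith(lines, "#")))
      return(.empty_models())
    gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                   error = function(e)
                     stop("failed to parse GFF3 '", gff, "': ",
                          conditionMessage(e), call. = FALSE))
  } else gr <- gff
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  if (length(genes_gr) == 0L) return(.empty_models())
  tx_gr <- gr[type %in% c("mRNA", "transcript")]
  first_parent <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  tx2gene <- stats::setNames(first_parent(tx_gr), tx_gr$ID)

  parts <- gr[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  ptx <- first_parent(parts)
  pgene <- ifelse(ptx %in% names(tx2gene), tx2gene[ptx], ptx)
  ptype <- as.character(parts$type)

  # reduce a part set per gene, returning a flat GRanges tagged with gene_id
  red_by_gene <- function(x, gid) {
    if (length(x) == 0L)
      return(GenomicRanges::GRanges(gene_id = character(0)))
    grl <- GenomicRanges::reduce(S4Vectors::split(GenomicRanges::granges(x),
                                                  gid))
    flat <- unlist(grl, use.names = TRUE)
    flat$gene_id <- names(flat)
    names(flat) <- NULL
    flat
  }
  ex <- red_by_gene(parts[ptype == "exon"], pgene[ptype == "exon"])
  cds <- red_by_gene(parts[ptype == "CDS"], pgene[ptype == "CDS"])
  u3 <- red_by_gene(parts[ptype == "three_prime_UTR"],
                    pgene[ptype == "three_prime_UTR"])
  u5 <- red_by_gene(parts[ptype == "five_prime_UTR"],
                    pgene[ptype == "five_prime_UTR"])

  # genes with a CDS but no annotated UTRs: infer UTR = exon minus CDS,
  # split by side relative to the CDS in transcript orientation
  need <- setdiff(intersect(unique(cds$gene_id), unique(ex$gene_id)),
                  c(unique(u3$gene_id), unique(u5$gene_id)))
  for (gid in need) {
    exg <- ex[ex$gene_id == gid]
    cdsg <- cds[cds$gene_id == gid]
    rest <- GenomicRanges::setdiff(exg, cdsg, ignore.strand = TRUE)
    if (length(rest) == 0L) next
    st <- as.character(GenomicRanges::strand(exg))[1]
    GenomicRanges::strand(rest) <- st
    after <- GenomicRanges::start(rest) > max(GenomicRanges::end(cdsg))
    before <- GenomicRanges::end(rest) < min(GenomicRanges::start(cdsg))
    n3 <- rest[if (st == "+") after else before]
    n5 <- rest[if (st == "+") before else after]
    if (length(n3)) { n3$gene_id <- gid; u3 <- c(u3, n3) }
    if (length(n5)) { n5$gene_id <- gid; u5 <- c(u5, n5) }
  }

  # introns: gene span minus exons (vectorised over genes with exons)
  gidx <- match(unique(ex$gene_id), genes_gr$ID)
  gsub <- GenomicRanges::granges(genes_gr[gidx])
  ex_grl <- S4Vectors::split(GenomicRanges::granges(ex), ex$gene_id)
  ex_grl <- ex_grl[unique(ex$gene_id)]
  introns <- GenomicRanges::psetdiff(gsub, ex_grl)
  intr <- unlist(introns, use.names = FALSE)
  ng <- lengths(introns)
  if (length(intr)) intr$gene_id <- rep(unique(ex$gene_id), ng)

  tag <- function(x, category) {
    if (length(x)) x$category <- category
    x
  }
  feat <- list(tag(cds, "exon"), tag(u3, "three_prime_utr"),
               tag(u5, "five_prime_utr"),
               if (length(intr)) tag(intr, "intron") else NULL)
  feat <- feat[!vapply(feat, is.null, logical(1))]
  feat <- feat[vapply(feat, length, integer(1)) > 0L]
  features <- if (length(feat)) do.call(c, unname(feat)) else
    GenomicRanges::GRanges()
  genes <- data.frame(
    gene_id = genes_gr$ID,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr) - 1L,
    stringsAsFactors = FALSE)
  structure(list(genes = genes, features = features), class = "gene_models")
}

.empty_models <- function() {
  structure(list(genes = data.frame(gene_id = character(0),
                                    chrom = character(0),
                                    strand = character(0),
                                    start = integer(0), end = integer(0)),
                 features = GenomicRanges::GRanges()),
            class = "gene_models")
}

.category_levels <- c("three_prime_utr", "five_prime_utr", "exon", "intron",
                      "intergenic")

#' Assign pA clusters to gene features
#'
#' Each cluster's representative position is matched against same-strand
#' genes. Category precedence across annotations: three_prime_utr >
#' five_prime_utr > exon (CDS-bearing) > intron; a position inside a gene
#' span but in no annotated feature is intronic; outside every same-strand
#' gene it is intergenic. Among overlapping candidate genes the gene whose
#' 3'UTR contains the site wins, else the gene with the closest 3' end
#' (ties broken by gene_id).
#'
#' @param clusters Cluster data frame (needs cluster_id, chrom, strand,
#'   representative_position).
#' @param models A \code{"gene_models"} object.
#' @return Data frame: cluster_id, gene_id (NA if intergenic), category.
#' @export
assign_feature <- function(clusters, models) {
  n <- nrow(clusters)
  out <- data.frame(cluster_id = clusters$cluster_id,
                    gene_id = rep(NA_character_, n),
                    category = rep("intergenic", n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(models$genes) == 0L) return(out)
  pts <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = clusters$representative_position + 1L,
                              width = 1L),
    strand = clusters$strand)

  cand <- list()
  if (length(models$features)) {
    hit <- GenomicRanges::findOverlaps(pts, models$features)
    if (length(hit))
      cand[[1]] <- data.frame(
        cluster = S4Vectors::queryHits(hit),
        gene_id = models$features$gene_id[S4Vectors::subjectHits(hit)],
        category = models$features$category[S4Vectors::subjectHits(hit)],
        stringsAsFactors = FALSE)
  }
  genes_gr <- GenomicRanges::GRanges(
    seqnames = models$genes$chrom,
    ranges = IRanges::IRanges(start = models$genes$start + 1L,
                              end = models$genes$end + 1L),
    strand = models$genes$strand)
  ghit <- GenomicRanges::findOverlaps(pts, genes_gr)
  if (length(ghit))
    cand[[length(cand) + 1L]] <- data.frame(
      cluster = S4Vectors::queryHits(ghit),
      gene_id = models$genes$gene_id[S4Vectors::subjectHits(ghit)],
      category = "intron",   # span-only fallback; real features outrank it
      stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(out)
  cand <- do.call(rbind, cand)
  cand$rank <- match(cand$category, .category_levels)
  # per (cluster, gene): best category
  key <- paste(cand$cluster, cand$gene_id, sep = "\r")
  best <- tapply(cand$rank, key, min)
  cand <- cand[!duplicated(key), ]
  cand$rank <- as.vector(best[paste(cand$cluster, cand$gene_id, sep = "\r")])
  cand$category <- .category_levels[cand$rank]
  # gene 3' end distance for tie-breaking between overlapping genes
  gidx <- match(cand$gene_id, models$genes$gene_id)
  g3 <- ifelse(models$genes$strand[gidx] == "+", models$genes$end[gidx],
               models$genes$start[gidx])
  cand$dist3 <- abs(clusters$representative_position[cand$cluster] - g3)
  o <- order(cand$cluster,
             cand$category != "three_prime_utr",  # genes holding it in 3'UTR first
             cand$dist3, cand$gene_id)
  cand <- cand[o, ]
  pick <- cand[!duplicated(cand$cluster), ]
  out$gene_id[pick$cluster] <- pick$gene_id
  out$category[pick$cluster] <- pick$category
  out
}

#' Per-gene APA summary
#'
#' Counts distinct clusters per gene, bins the count into the classes
#' 1/2/3/4/5/>5, flags genes with two or more sites as APA-regulated, and
#' classifies the APA type (see \code{\link{classify_apa_type}}).
#'
#' @param assignments Output of \code{\link{assign_feature}}; needs the
#'   clusters' positions/strands for distal-site logic, so pass
#'   \code{clusters} too.
#' @param clusters The cluster data frame that was assigned.
#' @return List: \code{per_gene} data frame (gene_id, n_sites, count_class,
#'   is_apa, apa_type), \code{class_fractions} (named, over genes with >= 1
#'   site), \code{apa_fraction}.
#' @export
summarize_gene_apa <- function(assignments, clusters) {
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  if (nrow(a) == 0L)
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_sites = integer(0),
                                      count_class = character(0),
                                      is_apa = logical(0),
                                      apa_type = character(0)),
                class_fractions = stats::setNames(numeric(6),
                                                  c("1", "2", "3", "4", "5", ">5")),
                apa_fraction = NaN))
  ci <- match(a$cluster_id, clusters$cluster_id)
  a$position <- clusters$representative_position[ci]
  a$strand <- clusters$strand[ci]
  per <- lapply(split(a, a$gene_id), function(d) {
    d <- d[!duplicated(d$cluster_id), ]
    n <- nrow(d)
    data.frame(gene_id = d$gene_id[1], n_sites = n,
               count_class = if (n > 5L) ">5" else as.character(n),
               is_apa = n >= 2L,
               apa_type = classify_apa_type(d$category, d$position,
                                            d$strand[1]),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, per)
  rownames(per_gene) <- NULL
  cls <- factor(per_gene$count_class, levels = c("1", "2", "3", "4", "5", ">5"))
  list(per_gene = per_gene,
       class_fractions = table(cls) / nrow(per_gene),
       apa_fraction = mean(per_gene$is_apa))
}

#' Classify a gene's APA type
#'
#' \code{single} for one site; \code{tandem_3utr} when all sites are in the
#' 3'UTR (only UTR length varies); \code{five_utr_apa} / \code{cds_apa} /
#' \code{intronic_apa} when at least one site falls in that category and the
#' distal (transcript 3'-most) site is in the 3'UTR, with precedence
#' five_utr_apa > cds_apa > intronic_apa (the 5'-most deviation names the
#' type); anything else is \code{mixed}. Invariant to the order in which the
#' sites are listed.
#'
#' @param categories Character vector of feature categories of the gene's
#'   sites.
#' @param positions Genomic representative positions (same length).
#' @param strand Gene strand ("+" or "-").
#' @return One of single / tandem_3utr / five_utr_apa / cds_apa /
#'   intronic_apa / mixed.
#' @export
classify_apa_type <- function(categories, positions, strand) {
  if (length(categories) == 1L) return("single")
  distal <- if (strand == "+") which.max(positions) else which.min(positions)
  if (all(categories == "three_prime_utr")) return("tandem_3utr")
  if (categories[distal] == "three_prime_utr") {
    if (any(categories == "five_prime_utr")) return("five_utr_apa")
    if (any(categories == "exon")) return("cds_apa")
    if (any(categories == "intron")) return("intronic_apa")
  }
  "mixed"
}

#' Category fractions of assigned clusters
#'
#' Fractions of gene-linked clusters per feature category (the four-way
#' genic split) plus the genic/intergenic split over all clusters.
#'
#' @param assignments Output of \code{\link{assign_feature}}.
#' @return List: \code{genic_fractions} (named, sums to 1 over genic
#'   clusters), \code{genic_fraction}, \code{intergenic_fraction}.
#' @export
category_fractions <- function(assignments) {
  genic <- assignments$category != "intergenic"
  lv <- setdiff(.category_levels, "intergenic")
  tab <- table(factor(assignments$category[genic], levels = lv))
  list(genic_fractions = if (sum(genic)) tab / sum(genic) else tab,
       genic_fraction = mean(genic),
       intergenic_fraction = mean(!genic))
}

#' Per-chromosome gene and site counts
#'
#' @param clusters Cluster data frame.
#' @param models A \code{"gene_models"} object.
#' @return Data frame: chrom, n_genes, n_sites, ratio (NA when a chromosome
#'   has no annotated gene), with a genome-wide "total" row appended.
#' @export
chromosome_summary <- function(clusters, models) {
  chroms <- sort(unique(c(clusters$chrom, models$genes$chrom)))
  ng <- table(factor(models$genes$chrom, levels = chroms))
  ns <- table(factor(clusters$chrom, levels = chroms))
  out <- data.frame(chrom = chroms, n_genes = as.integer(ng),
                    n_sites = as.integer(ns), stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$n_genes > 0, out$n_sites / out$n_genes, NA_real_)
  tot <- data.frame(chrom = "total", n_genes = nrow(models$genes),
                    n_sites = nrow(clusters),
                    ratio = if (nrow(models$genes) > 0)
                      nrow(clusters) / nrow(models$genes) else NA_real_)
  rbind(out, tot)
}
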