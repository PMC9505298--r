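## Sequence structure around cleavage sites: flank extraction, positional
## mono-/dinucleotide profiles, hexamer positional scans with signal/noise
## classification, PAS assignment and usage, chi-square tests against the
## genomic background, and downstream U/GU enrichment.
##
## All genomic computation is in the DNA alphabet; hexamers and profile
## alphabets are reported in RNA (T -> U) at the output layer.

#' Extract sense-strand flanks around cluster representatives
#'
#' A flank is the (2*halfwidth+1)-nt sense-strand window covering positions
#' -halfwidth..+halfwidth relative to the cleavage base (position 0). For -
#' strand clusters the genomic window is reverse-complemented so upstream is
#' transcript 5'. Out-of-contig positions are masked with N and excluded
#' from every downstream denominator.
#'
#' @param clusters Cluster data frame (\code{\link{cluster_events}}) or any
#'   data frame with cluster_id, chrom, strand, representative_position.
#' @param genome Genome (named character vector or \code{DNAStringSet}).
#' @param halfwidth Half window width, nt (default 100).
#' @return Data frame (cluster_id, chrom, strand, position, flank) with
#'   attribute \code{halfwidth}.
#' @export
extract_flanks <- function(clusters, genome, halfwidth = 100L) {
  genome <- .genome_strings(genome)
  missing_chrom <- setdiff(unique(clusters$chrom), names(genome))
  if (length(missing_chrom))
    stop("contig(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  p <- clusters$representative_position
  g <- genome[clusters$chrom]
  glen <- nchar(genome)[clusters$chrom] # lengths once per chrom, then lookup
  s <- p - halfwidth
  e <- p + halfwidth
  left_pad <- pmax(0L, -s)
  right_pad <- pmax(0L, e - (glen - 1L))
  raw <- substring(g, pmax(s, 0L) + 1L, pmin(e, glen - 1L) + 1L)
  fwd <- paste0(strrep("N", left_pad), raw, strrep("N", right_pad))
  minus <- clusters$strand == "-"
  if (any(minus)) fwd[minus] <- .revcomp(fwd[minus])
  out <- data.frame(cluster_id = clusters$cluster_id, chrom = clusters$chrom,
                    strand = clusters$strand, position = p, flank = fwd,
                    stringsAsFactors = FALSE)
  attr(out, "halfwidth") <- as.integer(halfwidth)
  out
}

.flank_halfwidth <- function(flanks) {
  hw <- attr(flanks, "halfwidth")
  if (is.null(hw)) (nchar(flanks$flank[1]) - 1L) %/% 2L else hw
}

#' Positional nucleotide or dinucleotide profile
#'
#' Per-position symbol frequencies over all unmasked flanks. Order 2 counts
#' overlapping dinucleotides indexed by their first base's position
#' (-halfwidth..halfwidth-1). At every position with unmasked count > 0 the
#' frequencies sum to 1.
#'
#' @param flanks Output of \code{\link{extract_flanks}}.
#' @param order 1 (mononucleotide) or 2 (dinucleotide).
#' @return List of class \code{"profile_matrix"}: \code{freq} (alphabet x
#'   position matrix, RNA rownames), \code{count} (unmasked flanks per
#'   position), \code{positions}, \code{order}.
#' @export
nucleotide_profile <- function(flanks, order = 1L) {
  stopifnot(order %in% c(1L, 2L), nrow(flanks) > 0L)
  hw <- .flank_halfwidth(flanks)
  m <- matrix(unlist(strsplit(flanks$flank, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(flanks), byrow = TRUE)
  if (order == 2L) {
    m <- matrix(paste0(m[, -ncol(m)], m[, -1L]), nrow = nrow(m))
    alphabet <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0))
    positions <- seq(-hw, hw - 1L)
  } else {
    alphabet <- c("A", "C", "G", "T")
    positions <- seq(-hw, hw)
  }
  freq <- matrix(0, nrow = length(alphabet), ncol = length(positions),
                 dimnames = list(.dna2rna(alphabet), positions))
  count <- integer(length(positions))
  for (j in seq_along(positions)) {
    col <- m[, j]
    ok <- col %in% alphabet   # drops anything containing N
    count[j] <- sum(ok)
    if (count[j] > 0L)
      freq[, j] <- tabulate(factor(col[ok], levels = alphabet),
                            nbins = length(alphabet)) / count[j]
  }
  structure(list(freq = freq, count = count, positions = positions,
                 order = order, n_flanks = nrow(flanks)),
            class = "profile_matrix")
}

#' Positional hexamer scan
#'
#' Counts exact hexamer occurrences by 5'-base position over a scan range
#' upstream of the cleavage base. An occurrence at position p spans p..p+5
#' and must lie wholly within the scan range; windows containing masked (N)
#' bases are skipped. Also reports, per hexamer, the number of sites with at
#' least one occurrence in the range.
#'
#' @param flanks Output of \code{\link{extract_flanks}}.
#' @param scan_range Scan interval relative to the cleavage base, default
#'   \code{c(-50, -1)} (covering the 50 bp upstream).
#' @return List of class \code{"hexamer_scan"}: \code{counts} (data frame
#'   hexamer [RNA], position, count), \code{sites_with} (named integer),
#'   \code{positions} (scanned 5'-base positions), \code{n_flanks}.
#' @export
hexamer_position_scan <- function(flanks, scan_range = c(-50L, -1L)) {
  hw <- .flank_halfwidth(flanks)
  starts <- if (scan_range[2] - 5L >= scan_range[1])
    seq(scan_range[1], scan_range[2] - 5L) else integer(0)
  # a whole hexamer must fit inside the flank
  starts <- starts[starts >= -hw & starts + 5L <= hw]
  if (length(starts) == 0L)
    return(structure(list(counts = data.frame(hexamer = character(0),
                                              position = integer(0),
                                              count = integer(0)),
                          sites_with = integer(0), positions = integer(0),
                          n_flanks = nrow(flanks)), class = "hexamer_scan"))
  hex_by_pos <- lapply(starts, function(x) {
    i <- x + hw + 1L
    substr(flanks$flank, i, i + 5L)
  })
  hex <- unlist(hex_by_pos, use.names = FALSE)
  pos <- rep(starts, each = nrow(flanks))
  site <- rep.int(seq_len(nrow(flanks)), length(starts))
  ok <- !grepl("N", hex, fixed = TRUE)
  hex <- hex[ok]; pos <- pos[ok]; site <- site[ok]
  tab <- table(hexamer = hex, position = pos)
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts)[3] <- "count"
  counts <- counts[counts$count > 0L, ]
  counts$position <- as.integer(as.character(counts$position))
  counts$hexamer <- .dna2rna(counts$hexamer)
  counts <- counts[order(counts$hexamer, counts$position), ]
  rownames(counts) <- NULL
  sw <- tapply(site, .dna2rna(hex), function(s) length(unique(s)))
  structure(list(counts = counts,
                 sites_with = stats::setNames(as.integer(sw), names(sw)),
                 positions = starts, n_flanks = nrow(flanks)),
            class = "hexamer_scan")
}

#' Classify a hexamer's positional distribution as signal or noise
#'
#' A polyadenylation signal shows a sharp positional peak in the canonical
#' window upstream of the cleavage base, while a hexamer scattered at low
#' frequency across positions is noise. The peak score is the maximal
#' positional count inside \code{peak_range} divided by (median positional
#' count over the whole scan + 1); a hexamer is classified "signal" iff the
#' score reaches \code{threshold} and the peak lies inside \code{peak_range}.
#'
#' @param scan Output of \code{\link{hexamer_position_scan}}.
#' @param hexamer Hexamer to classify (RNA or DNA spelling).
#' @param peak_range Positional window for a credible PAS peak
#'   (default \code{c(-40, -10)}).
#' @param threshold Peak-score threshold (default 5).
#' @return List: class ("signal"/"noise"), peak_position, peak_score.
#' @export
classify_hexamer_signal <- function(scan, hexamer, peak_range = c(-40L, -10L),
                                    threshold = 5) {
  hexamer <- .dna2rna(hexamer)
  cnt <- stats::setNames(rep(0L, length(scan$positions)),
                         as.character(scan$positions))
  rows <- scan$counts[scan$counts$hexamer == hexamer, ]
  cnt[as.character(rows$position)] <- rows$count
  med <- stats::median(cnt)
  in_peak <- scan$positions >= peak_range[1] & scan$positions <= peak_range[2]
  if (!any(in_peak) || all(cnt[in_peak] == 0L))
    return(list(class = "noise", peak_position = NA_integer_, peak_score = 0))
  peak_idx <- which(in_peak)[which.max(cnt[in_peak])]
  peak_pos <- scan$positions[peak_idx]
  score <- max(cnt[in_peak]) / (med + 1)
  list(class = if (score >= threshold) "signal" else "noise",
       peak_position = peak_pos, peak_score = unname(score))
}

#' Assign a PAS hexamer to each site
#'
#' Searches the 14 canonical PAS hexamers wholly within the
#' \code{window}-nt window upstream of the cleavage base (positions
#' -window..-1). The first hexamer present in priority order (AAUAAA
#' highest, then the reference usage ranking; see \code{\link{pas_hexamers}})
#' is assigned. When the assigned hexamer occurs several times, the
#' occurrence closest to the modal PAS region is chosen: the largest offset
#' <= -11, else the offset nearest -11. Sites containing none of the 14 are
#' assigned \code{"none"} ("Other").
#'
#' @param flanks Output of \code{\link{extract_flanks}}.
#' @param window Upstream search window, nt (default 40).
#' @return Data frame: cluster_id, pas (RNA or "none"), offset (5'-base
#'   position of the assigned occurrence, NA for none).
#' @export
assign_pas <- function(flanks, window = 40L) {
  hw <- .flank_halfwidth(flanks)
  win <- substr(flanks$flank, hw + 1L - window, hw)
  n <- length(win)
  pas <- rep("none", n)
  offset <- rep(NA_integer_, n)
  unassigned <- rep(TRUE, n)
  for (motif in pas_hexamers("DNA")) {
    if (!any(unassigned)) break
    hits <- .find_all(win[unassigned], motif)
    got <- lengths(hits) > 0L
    if (!any(got)) next
    idx <- which(unassigned)[got]
    offset[idx] <- vapply(hits[got], function(h) {
      o <- h - 1L - window          # window index 1 is position -window
      late <- o[o <= -11L]
      if (length(late)) max(late) else min(o)
    }, integer(1))
    pas[idx] <- .dna2rna(motif)
    unassigned[idx] <- FALSE
  }
  data.frame(cluster_id = flanks$cluster_id, pas = pas, offset = offset,
             stringsAsFactors = FALSE)
}

#' PAS usage frequency table
#'
#' Percentage of sites assigned each PAS hexamer, plus "Other" for sites
#' with none of the 14; percentages are over all sites and sum to 100 up to
#' rounding.
#'
#' @param pascalls Output of \code{\link{assign_pas}}.
#' @return Data frame: hexamer (RNA, "Other" last), n, percent.
#' @export
usage_frequency_table <- function(pascalls) {
  if (nrow(pascalls) == 0L)
    return(data.frame(hexamer = character(0), n = integer(0),
                      percent = numeric(0)))
  lv <- c(pas_hexamers(), "none")
  n <- tabulate(factor(pascalls$pas, levels = lv), nbins = length(lv))
  data.frame(hexamer = c(pas_hexamers(), "Other"), n = n,
             percent = 100 * n / nrow(pascalls), stringsAsFactors = FALSE)
}

#' Expected background nucleotide frequencies from GC content
#'
#' @param gc Genomic GC fraction.
#' @return Named vector (A, C, G, U): P(G)=P(C)=gc/2, P(A)=P(U)=(1-gc)/2.
#' @examples
#' background_freqs(0.364)  # A/U 0.318, C/G 0.182
#' @export
background_freqs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
}

#' Chi-square test of a positional frequency against the genome background
#'
#' One-degree-of-freedom goodness of fit on the two-cell split (is the
#' nucleotide vs is not) with expected proportions from the GC-content
#' background model.
#'
#' @param profile A \code{"profile_matrix"} (order 1) from
#'   \code{\link{nucleotide_profile}}.
#' @param position Position relative to the cleavage base.
#' @param nucleotide One of "A", "C", "G", "U" (or "T").
#' @param gc Background GC fraction (default 0.364).
#' @return List: position, nucleotide, n, observed_freq, expected_freq,
#'   statistic, p_value. With unmasked count n = 0 the statistic and p are
#'   NA (undefined, not an error).
#' @export
chisq_vs_background <- function(profile, position, nucleotide, gc = 0.364) {
  stopifnot(profile$order == 1L)
  nucleotide <- .dna2rna(toupper(nucleotide))
  j <- match(position, profile$positions)
  if (is.na(j)) stop("position ", position, " outside the profiled range")
  n <- profile$count[j]
  ef <- unname(background_freqs(gc)[nucleotide])
  if (n == 0L)
    return(list(position = position, nucleotide = nucleotide, n = 0L,
                observed_freq = NA_real_, expected_freq = ef,
                statistic = NA_real_, p_value = NA_real_))
  of <- unname(profile$freq[nucleotide, j])
  x <- round(of * n)
  ht <- suppressWarnings(stats::chisq.test(c(x, n - x), p = c(ef, 1 - ef)))
  list(position = position, nucleotide = nucleotide, n = n,
       observed_freq = of, expected_freq = ef,
       statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Chi-square tests across all positions and nucleotides
#'
#' Runs \code{\link{chisq_vs_background}} for every profiled position and
#' nucleotide. No multiple-testing correction is applied to the headline
#' p-values; a Bonferroni-adjusted column is included for transparency.
#'
#' @inheritParams chisq_vs_background
#' @return Data frame with one row per (position, nucleotide).
#' @export
chisq_profile <- function(profile, gc = 0.364) {
  grid <- expand.grid(position = profile$positions,
                      nucleotide = rownames(profile$freq),
                      stringsAsFactors = FALSE)
  rows <- mapply(function(p, nt) chisq_vs_background(profile, p, nt, gc),
                 grid$position, grid$nucleotide, SIMPLIFY = FALSE)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Downstream U/GU enrichment report
#'
#' Descriptive summary of the downstream sequence element: mean U frequency
#' (and UU/GU dinucleotide frequency when a dinucleotide profile is given)
#' over a downstream window, against the GC-content background expectation,
#' plus the downstream position of maximal U and a distal comparison window.
#'
#' @param mono Order-1 \code{"profile_matrix"}.
#' @param di Optional order-2 profile for the UU/GU means.
#' @param gc Background GC fraction.
#' @param window Downstream window (default \code{c(3, 27)}).
#' @param far_window Distal downstream comparison window
#'   (default \code{c(60, 84)}).
#' @return List of window means, background expectations and the position of
#'   maximal downstream U.
#' @export
dse_enrichment <- function(mono, di = NULL, gc = 0.364,
                           window = c(3L, 27L), far_window = c(60L, 84L)) {
  stopifnot(mono$order == 1L)
  sel <- function(prof, w) prof$positions >= w[1] & prof$positions <= w[2]
  u_win <- mean(mono$freq["U", sel(mono, window)])
  u_far <- mean(mono$freq["U", sel(mono, far_window)])
  down <- mono$positions > 0
  argmax_u <- mono$positions[down][which.max(mono$freq["U", down])]
  out <- list(mean_u_window = u_win, mean_u_far = u_far,
              expected_u = unname(background_freqs(gc)["U"]),
              max_u_position = argmax_u,
              window = window, far_window = far_window)
  if (!is.null(di)) {
    stopifnot(di$order == 2L)
    out$mean_uu_window <- mean(di$freq["UU", sel(di, window)])
    out$mean_gu_window <- mean(di$freq["GU", sel(di, window)])
    out$expected_uu <- unname(background_freqs(gc)["U"]^2)
    out$expected_gu <- unname(background_freqs(gc)["G"] *
                              background_freqs(gc)["U"])
  }
  out
}

#' Write profile, scan and usage outputs as TSV
#'
#' @param profile A \code{"profile_matrix"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  long <- data.frame(
    position = rep(profile$positions, each = nrow(profile$freq)),
    symbol = rep(rownames(profile$freq), length(profile$positions)),
    frequency = as.vector(profile$freq),
    n = rep(profile$count, each = nrow(profile$freq)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
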