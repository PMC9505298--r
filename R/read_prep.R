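#' Detect and trim terminal poly(A)/poly(T) tails
#'
#' A read carries poly(A) evidence if it ends in an adenine run (3' A tail)
#' or starts with a thymine run (reverse-complemented tail) of at least
#' \code{min_tail} nt. The tail is the maximal terminal homopolymer run,
#' with zero mismatches; N terminates a run. If both ends qualify the longer
#' run wins, ties go to the 3' A tail. Reads called \code{five_prime_T} are
#' reverse-complemented so the returned \code{sense_sequence} is always in
#' transcript sense orientation.
#'
#' @param sequences Character vector of read sequences over A/C/G/T/N.
#' @param read_id Optional read identifiers (defaults to seq_along).
#' @param min_tail Minimum tail length in nt (default 10).
#' @param source_tag Evidence source label ("EST" or "long_read"), recycled.
#' @return Data frame (one row per read): read_id, tail_end
#'   (\code{"three_prime_A"}, \code{"five_prime_T"} or \code{"none"}),
#'   tail_length, trimmed_sequence (input orientation), sense_sequence,
#'   source_tag. For \code{tail_end == "none"} the sequence is untouched.
#' @examples
#' detect_tail(c("GGCTTACGAAAAAAAAAA", "TTTTTTTTTTTTACGGA"))
#' @export
detect_tail <- function(sequences, read_id = NULL, min_tail = 10L,
                        source_tag = "long_read") {
  stopifnot(min_tail >= 1L)
  if (is.null(read_id)) read_id <- as.character(seq_along(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN character in read(s): ",
         paste(utils::head(read_id[bad], 5L), collapse = ", "))
  runA <- .terminal_run(sequences, "A", "3p")
  runT <- .terminal_run(sequences, "T", "5p")
  # a pure-homopolymer read is all tail; never trim below an empty remainder
  n <- nchar(sequences)
  runA <- pmin(runA, n)
  runT <- pmin(runT, n)
  useA <- runA >= min_tail & runA >= runT   # tie -> 3' A
  useT <- runT >= min_tail & runT > runA
  tail_end <- ifelse(useA, "three_prime_A",
                     ifelse(useT, "five_prime_T", "none"))
  tail_length <- ifelse(useA, runA, ifelse(useT, runT, 0L))
  trimmed <- sequences
  trimmed[useA] <- substr(sequences[useA], 1L, n[useA] - runA[useA])
  trimmed[useT] <- substr(sequences[useT], runT[useT] + 1L, n[useT])
  sense <- trimmed
  if (any(useT)) sense[useT] <- .revcomp(trimmed[useT])
  data.frame(read_id = read_id, tail_end = tail_end,
             tail_length = as.integer(tail_length),
             trimmed_sequence = trimmed, sense_sequence = sense,
             source_tag = rep_len(source_tag, length(sequences)),
             stringsAsFactors = FALSE)
}

#' Prepare a batch of reads: tail detection, trimming, orientation
#'
#' Reads FASTA/FASTQ (or takes sequences directly), applies
#' \code{\link{detect_tail}} and reports per-source counts of raw and
#' poly(A)-tail-containing reads. Only tailed reads are retained in
#' \code{calls}.
#'
#' @param reads Path to a FASTA/FASTQ file (gzip transparent), a named
#'   character vector of sequences, or a data frame with read_id, sequence
#'   and (optionally) source_tag columns.
#' @param min_tail Minimum tail length (default 10).
#' @param source_tag Source label used when \code{reads} carries none.
#' @param format \code{"auto"}, \code{"fasta"} or \code{"fastq"} for file
#'   input.
#' @return List with \code{calls} (tail calls of tailed reads only) and
#'   \code{stats}: data frame of raw_count / tailed_count per source_tag.
#' @export
prepare_reads <- function(reads, min_tail = 10L, source_tag = "long_read",
                          format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (format == "auto")
      format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads,
                          ignore.case = TRUE)) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(reads, format = format)
    df <- data.frame(read_id = sub("\\s.*$", "", names(ss)),
                     sequence = as.character(ss),
                     source_tag = source_tag, stringsAsFactors = FALSE)
  } else if (is.data.frame(reads)) {
    df <- reads
    if (is.null(df$source_tag))
      df$source_tag <- rep_len(source_tag, nrow(df))
  } else {
    df <- data.frame(read_id = if (is.null(names(reads)))
                       as.character(seq_along(reads)) else names(reads),
                     sequence = unname(reads), source_tag = source_tag,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L)
    return(list(calls = detect_tail(character(0)),
                stats = data.frame(source_tag = character(0),
                                   raw_count = integer(0),
                                   tailed_count = integer(0))))
  calls <- detect_tail(df$sequence, df$read_id, min_tail = min_tail,
                       source_tag = df$source_tag)
  tailed <- calls$tail_end != "none"
  stats <- do.call(rbind, lapply(split(tailed, calls$source_tag), function(x)
    data.frame(raw_count = length(x), tailed_count = sum(x))))
  stats <- data.frame(source_tag = rownames(stats), stats,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls[tailed, , drop = FALSE], stats = stats)
}

#' Write prepared reads and a tail report
#'
#' Emits trimmed sense reads as FASTQ (constant quality) and a TSV tail
#' report (read_id, tail_end, tail_length).
#'
#' @param prep Output of \code{\link{prepare_reads}}.
#' @param out_prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_prepared_reads <- function(prep, out_prefix) {
  fq <- paste0(out_prefix, ".trimmed.fastq")
  tsv <- paste0(out_prefix, ".tails.tsv")
  ss <- Biostrings::DNAStringSet(prep$calls$sense_sequence)
  names(ss) <- prep$calls$read_id
  Biostrings::writeXStringSet(
    ss, fq, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(ss))))
  utils::write.table(prep$calls[, c("read_id", "tail_end", "tail_length")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fq, tsv))
}
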