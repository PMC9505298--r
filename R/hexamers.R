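#' Canonical PAS hexamers
#'
#' The 14 polyadenylation-signal (PAS) hexamers tracked by the package, in
#' priority order: the canonical AAUAAA first, then its common variants in
#' descending order of reported usage. All PAS bookkeeping (usage tables,
#' assignment priority, generator usage vectors) uses this order; sites in
#' which none of the 14 occurs are reported as \code{"none"} ("Other").
#'
#' @param alphabet \code{"RNA"} (default, U) or \code{"DNA"} (T).
#' @return Character vector of 14 hexamers.
#' @examples
#' pas_hexamers()
#' pas_hexamers("DNA")[1]  # "AATAAA"
#' @export
pas_hexamers <- function(alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  hx <- c("AAUAAA", "AUUAAA", "UAUAAA", "AGUAAA", "AAGAAA", "AAUAUA",
          "AAUACA", "CAUAAA", "GAUAAA", "AAUGAA", "UUUAAA", "ACUAAA",
          "AAUAGA", "AAAAAG")
  if (alphabet == "DNA") chartr("U", "T", hx) else hx
}

#' Reference PAS usage probabilities
#'
#' Published usage frequencies of the 14 PAS hexamers (plus the "none" class)
#' in the reference insect 3' end dataset, normalised to sum to one. Used as
#' the default \code{hexamer_usage} of the synthetic-data generator.
#'
#' @return Named numeric vector over \code{c(pas_hexamers(), "none")},
#'   summing to 1.
#' @export
pas_usage_reference <- function() {
  pct <- c(51.64, 12.15, 4.38, 4.17, 2.63, 2.42, 2.32, 2.00, 2.01, 1.64,
           1.25, 1.19, 1.05, 1.03, 10.13)
  names(pct) <- c(pas_hexamers(), "none")
  pct / sum(pct)
}

## -- internal sequence helpers -----------------------------------------------

# reverse complement of plain character vectors (DNA alphabet + N)
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.dna2rna <- function(x) chartr("T", "U", x)
.rna2dna <- function(x) chartr("U", "T", x)

# length of terminal homopolymer run of `base`; vectorised.
# side = "3p": run at the string end; "5p": at the start. N (or any other
# character) terminates a run.
.terminal_run <- function(x, base, side = c("3p", "5p")) {
  side <- match.arg(side)
  pat <- if (side == "3p") paste0(base, "+$") else paste0("^", base, "+")
  nchar(x) - nchar(sub(pat, "", x, perl = TRUE))
}

# number of occurrences of a single character in each string
.count_char <- function(x, ch) {
  nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
}

# all (overlapping) start positions of `pattern` in each string; returns a
# list of integer vectors (1-based)
.find_all <- function(x, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)
  lapply(m, function(p) {
    p <- as.integer(p)
    p[p > 0L]
  })
}

# draw i.i.d. bases with P(G)=P(C)=gc/2, P(A)=P(T)=(1-gc)/2
.draw_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.stopifnot_prob <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(what, " must be a probability vector summing to 1 (got sum ",
         format(sum(p)), ")", call. = FALSE)
  invisible(p)
}
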