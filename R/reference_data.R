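#' Published reference summary tables
#'
#' Summary tables of the reference *Spodoptera frugiperda* 3' end dataset
#' (EST + full-length transcriptome evidence), bundled as plain text:
#' \code{"counts"} — per-source read-processing counters (raw reads,
#' poly(A)-tailed reads, uniquely mapped reads, pA clusters);
#' \code{"pas_usage"} — the published PAS hexamer usage percentages;
#' \code{"distribution"} — genomic-distribution and APA summary quantities
#' (genic/intergenic splits, feature-category percentages, per-chromosome
#' extremes, cluster member-count percentages).
#'
#' These are inputs for arithmetic-consistency checks and for configuring
#' the synthetic generator; the package never uses them to shortcut a
#' computation.
#'
#' @param which Table name.
#' @return A data frame.
#' @export
pasite_reference <- function(which = c("counts", "pas_usage",
                                       "distribution")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("reference_", which, ".tsv"),
                      package = "pasite", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
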