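#' CRISPR locus summary fixture for the 14 M. aeruginosa genomes
#'
#' The published per-locus summary of the species' 71 CRISPR loci: strain,
#' locus id, repeat sequence and family, repeat-unit count, spacer length
#' range, locus length and cas-gene complement. The `cas_genes` column is a
#' synthetic reconstruction: the published material prints each locus's
#' subtype and cas gene count together with the four subtype operon
#' architectures, and this column lists, for each locus, that many genes of
#' its subtype's architecture. It exists so the subtype caller can be
#' exercised against the published calls; it is not a deposited annotation.
#'
#' @return Data frame with 71 rows.
#' @export
reference_loci <- function() {
  utils::read.delim(system.file("extdata", "microcystis_loci.tsv",
                                package = "crisprscape"),
                    stringsAsFactors = FALSE)
}

#' The 16 distinct direct-repeat strings of the locus fixture
#'
#' @return Named character vector (names are the published variant labels,
#'   e.g. `DR1a` for the reverse-complement variant of DR1).
#' @export
reference_repeats <- function() {
  ss <- Biostrings::readBStringSet(system.file("extdata", "microcystis_repeats.fa",
                                               package = "crisprscape"))
  setNames(as.character(ss), names(ss))
}
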