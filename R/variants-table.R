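#' Bundled survey of observed Y-STR allele sequence variants
#'
#' The package ships a 37-row table of previously undocumented allele
#' sequences observed in a 41-male population survey (13 African American,
#' 12 Caucasian, 16 Hispanic): 19 nominal allele variants (sequences of
#' alleles that already have a documented sequence) and 18 novel allele
#' sequences (alleles with no documented sequence), each given as a
#' bracketed observed repeat motif with its nominal allele, coverage
#' range, per-population sample counts, variant type (RPV or intra-repeat
#' SNP) and associated haplogroups (annotation only). The table is used by
#' the test-suite and the acceptance checks as ground truth for the
#' decomposer and classifier.
#'
#' @param path Path to the TSV; defaults to the bundled copy.
#' @return A data frame with columns locus, allele, observed_motif,
#'   category (`nominal`/`novel`), coverage, AFA, CAU, HIS, variant_type
#'   and haplogroups.
#' @export
observed_variants <- function(path = system.file("extdata",
                                                 "observed_variants.tsv",
                                                 package = "ystrseq")) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
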