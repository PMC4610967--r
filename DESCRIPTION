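Package: ystrseq
Title: Sequence-Based Y-STR Allele Typing and Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sequence-based typing of Y-chromosome short tandem
    repeats (Y-STRs) from raw sequencing reads. Implements flank-anchored
    allele detection that genotypes STR alleles by repeat-region length while
    retaining their nucleotide sequences, template-guided decomposition of
    repeat regions into bracketed run-length notation, and classification of
    observed allele sequences against a known-allele catalog as documented
    sequences, repeat pattern variants (RPVs) or intra-repeat SNP variants,
    each flagged as a nominal allele variant or a novel allele sequence. A
    seeded paired-end read simulator with a per-base substitution error model
    provides ground-truth cohorts for end-to-end validation of the pipeline
    on a bundled panel of 28 forensically relevant Y-STR loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
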