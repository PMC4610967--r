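# Flank-anchored allele detection: locate both anchors in a read (either
# orientation), excise the intervening repeat region, call the allele by
# region length while retaining the sequence, and apply the coverage floor.

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Reverse complements, as a character vector.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file as a character vector of sequences
#'
#' @param path FASTQ file, optionally gzipped.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("failed to read FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  setNames(as.character(x), names(x))
}

# vectorized anchored extraction over one orientation: first occurrence of
# flank5, then first occurrence of flank3 downstream of it
.extract_oriented <- function(strs, flank5, flank3) {
  res <- rep(NA_character_, length(strs))
  p5 <- regexpr(flank5, strs, fixed = TRUE)
  idx <- which(p5 > 0L)
  if (length(idx)) {
    start <- p5[idx] + nchar(flank5)
    rest <- substr(strs[idx], start, nchar(strs[idx]))
    p3 <- regexpr(flank3, rest, fixed = TRUE)
    ok <- p3 > 0L
    res[idx[ok]] <- substr(rest[ok], 1L, p3[ok] - 1L)
  }
  res
}

# regions for a vector of reads; ambiguous double-orientation matches are
# dropped and counted
.extract_regions <- function(reads, reads_rc, locus) {
  fwd <- .extract_oriented(reads, locus$flank5, locus$flank3)
  rev <- .extract_oriented(reads_rc, locus$flank5, locus$flank3)
  ambiguous <- !is.na(fwd) & !is.na(rev)
  region <- ifelse(ambiguous, NA_character_,
                   ifelse(!is.na(fwd), fwd, rev))
  list(region = region, n_ambiguous = sum(ambiguous))
}

#' Extract the repeat region of a locus from one read
#'
#' Searches the read and its reverse complement for the locus's 5' anchor
#' followed by its 3' anchor and returns the intervening substring of the
#' matching orientation. Absence of either anchor is a normal outcome
#' (`NA`); a read matching in both orientations is ambiguous and dropped.
#'
#' @param read A single read sequence (ACGTN).
#' @param locus A `locus_definition`.
#' @param max_mismatch Number of mismatches tolerated per anchor
#'   (default 0, exact matching).
#' @return The repeat-region substring, or `NA` if not found/ambiguous.
#' @export
extract_repeat_region <- function(read, locus, max_mismatch = 0L) {
  stopifnot(length(read) == 1L, inherits(locus, "locus_definition"))
  if (max_mismatch == 0L) {
    return(.extract_regions(read, revcomp(read), locus)$region)
  }
  one <- function(s) {
    subj <- Biostrings::DNAString(s)
    m5 <- Biostrings::matchPattern(locus$flank5, subj,
                                   max.mismatch = max_mismatch)
    if (!length(m5)) return(NA_character_)
    start <- Biostrings::end(m5)[1] + 1L
    if (start > nchar(s)) return(NA_character_)
    m3 <- Biostrings::matchPattern(locus$flank3,
                                   Biostrings::subseq(subj, start),
                                   max.mismatch = max_mismatch)
    if (!length(m3)) return(NA_character_)
    substr(s, start, start + Biostrings::start(m3)[1] - 2L)
  }
  fwd <- one(read)
  rev <- one(revcomp(read))
  if (!is.na(fwd) && !is.na(rev)) return(NA_character_)
  if (!is.na(fwd)) fwd else rev
}

#' Call STR alleles for one sample from FASTQ reads
#'
#' For every locus, extracts repeat regions from all reads (mates are
#' processed independently), tallies identical extracted sequences, and
#' reports each distinct sequence supported by at least `min_coverage`
#' reads as one allele call, designated by region length. Multicopy loci
#' may legitimately yield several calls; single-copy loci yielding more
#' than one surviving sequence are all reported and flagged.
#'
#' @param fastq1 Path to the R1 FASTQ file (or a single-end file).
#' @param fastq2 Optional path to the mate file.
#' @param panel A `ystr_panel`.
#' @param min_coverage Minimum supporting reads per reported sequence
#'   (default 5).
#' @param sample_id,population Labels copied into the output.
#' @return A data frame of calls (sample_id, population, locus, allele,
#'   sequence, coverage, flagged) with a per-locus QC table (reads
#'   matched, ambiguous reads) in `attr(, "qc")`.
#' @export
call_sample <- function(fastq1, fastq2 = NULL, panel = ystr_panel(),
                        min_coverage = 5L, sample_id = "sample",
                        population = NA_character_) {
  stopifnot(inherits(panel, "ystr_panel"), min_coverage >= 1L)
  reads <- read_fastq(fastq1)
  if (!is.null(fastq2)) reads <- c(reads, read_fastq(fastq2))
  reads <- unname(toupper(reads))
  reads_rc <- revcomp(reads)
  calls <- list()
  qc <- list()
  for (locus in panel) {
    ex <- .extract_regions(reads, reads_rc, locus)
    regions <- ex$region[!is.na(ex$region)]
    qc[[length(qc) + 1L]] <- data.frame(
      locus = locus$name, reads_matched = length(regions),
      reads_ambiguous = ex$n_ambiguous, stringsAsFactors = FALSE)
    if (!length(regions)) next
    tab <- table(regions)
    tab <- tab[tab >= min_coverage]
    if (!length(tab)) next
    flag_multi <- !locus$multicopy && length(tab) > 1L
    for (i in seq_along(tab)) {
      seqi <- names(tab)[i]
      des <- tryCatch(format(length_to_designation(locus, nchar(seqi))),
                      error = function(e) NA_character_)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sample_id, population = population, locus = locus$name,
        allele = des, sequence = seqi, coverage = as.integer(tab[i]),
        flagged = flag_multi || is.na(des), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), population = character(),
               locus = character(), allele = character(),
               sequence = character(), coverage = integer(),
               flagged = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "qc") <- do.call(rbind, qc)
  out
}
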