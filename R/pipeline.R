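# End-to-end orchestration: simulate a cohort, call alleles per sample,
# compile unique sequences, classify, and write report tables.

#' Simulate a demonstration cohort to disk
#'
#' Thin wrapper over [simulate_cohort()]: writes one FASTQ pair per sample
#' plus `samples.tsv` (sample sheet) and `manifest.tsv` (ground truth)
#' under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param panel A `ystr_panel`.
#' @param n_afa,n_cau,n_his Samples per population (defaults 13/12/16).
#' @param coverage Read pairs per allele copy, or `"panel"` for the
#'   per-locus configured means.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for reproducible output.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulation <- function(out_dir, panel = ystr_panel(),
                           n_afa = 13L, n_cau = 12L, n_his = 16L,
                           coverage = 30, read_length = 250L,
                           error_rate = 0, seed = 1L) {
  cfg <- sim_config(read_length = read_length, coverage = coverage,
                    error_rate = error_rate, seed = seed)
  simulate_cohort(panel, cfg, out_dir = out_dir,
                  n_afa = n_afa, n_cau = n_cau, n_his = n_his)
}

#' Analyze a cohort of FASTQ samples
#'
#' Runs [call_sample()] for every sample in the sheet, combines the calls,
#' compiles unique sequences with [compile_unique_sequences()], and
#' optionally writes `report.tsv` (the unique-sequence variant table),
#' `calls.tsv` and `coverage_summary.tsv` (per-locus min/mean/max of
#' matched reads across samples) under `out_dir`.
#'
#' @param samples A sample sheet data frame with columns `sample_id`,
#'   `population`, `r1` and optionally `r2`; or the path of a TSV file
#'   with those columns (as written by [run_simulation()]).
#' @param panel A `ystr_panel`.
#' @param catalog A `ystr_catalog`.
#' @param min_coverage Coverage floor for allele calls (default 5).
#' @param out_dir Optional output directory for report files.
#' @return A list with `calls`, `report` and `coverage` data frames.
#' @export
run_analysis <- function(samples, panel = ystr_panel(),
                         catalog = ystr_catalog(), min_coverage = 5L,
                         out_dir = NULL) {
  if (is.character(samples)) {
    samples <- read.delim(samples, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  stopifnot(all(c("sample_id", "population", "r1") %in% names(samples)))
  all_calls <- list()
  qcs <- list()
  for (i in seq_len(nrow(samples))) {
    r2 <- if ("r2" %in% names(samples) && !is.na(samples$r2[i]) &&
              nzchar(samples$r2[i])) samples$r2[i] else NULL
    calls <- call_sample(samples$r1[i], r2, panel = panel,
                         min_coverage = min_coverage,
                         sample_id = samples$sample_id[i],
                         population = samples$population[i])
    if (!nrow(calls)) {
      warning("sample ", samples$sample_id[i], ": no alleles called")
    }
    qc <- attr(calls, "qc")
    qc$sample_id <- samples$sample_id[i]
    all_calls[[i]] <- calls
    qcs[[i]] <- qc
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  report <- compile_unique_sequences(calls, panel, catalog)
  qc <- do.call(rbind, qcs)
  agg <- lapply(split(qc$reads_matched, qc$locus), function(v) {
    data.frame(min_reads = min(v), mean_reads = round(mean(v), 1),
               max_reads = max(v))
  })
  coverage <- cbind(data.frame(locus = names(agg), stringsAsFactors = FALSE),
                    do.call(rbind, agg))
  coverage <- coverage[match(intersect(names(panel), coverage$locus),
                             coverage$locus), , drop = FALSE]
  rownames(coverage) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(coverage, file.path(out_dir, "coverage_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, report = report, coverage = coverage)
}

#' Classify a single sequence or decomposition at a locus
#'
#' Desk utility: accepts either a raw repeat-region sequence or a
#' bracketed decomposition (which is realized using the locus's spacer
#' fills), classifies it against the catalog, and prints the result.
#'
#' @param locus_name A panel locus name.
#' @param text A DNA sequence, or a bracketed decomposition string.
#' @param panel A `ystr_panel`.
#' @param catalog A `ystr_catalog`.
#' @return The `variant_classification`, invisibly.
#' @examples
#' \dontrun{
#' classify_one("DYS481", "[CTG]1[CTT]25")
#' }
#' @export
classify_one <- function(locus_name, text, panel = ystr_panel(),
                         catalog = ystr_catalog()) {
  locus <- panel[[locus_name]]
  if (is.null(locus)) {
    stop("unknown locus '", locus_name, "'", call. = FALSE)
  }
  seq <- if (grepl("[", text, fixed = TRUE)) {
    d <- parse_decomposition(text, locus$template$period)
    realize_sequence(d, spacer_fills = locus$spacer_fills)
  } else {
    toupper(gsub("[[:space:]]", "", text))
  }
  cls <- classify_sequence(locus, seq, catalog)
  print(cls)
  invisible(cls)
}
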