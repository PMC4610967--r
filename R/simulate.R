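# Seeded generator of ground-truth haplotypes, STR amplicons and paired-end
# reads, with a truth manifest for recovery testing. Fragments always span
# the amplicon (anchor to anchor) with uniformly jittered random context
# padding, roughly half the reads are emitted reverse-complemented, and
# substitution errors are applied i.i.d. per base. Base qualities are
# written as a constant high value: the caller is sequence-only.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Realize the DNA sequence of a decomposition
#'
#' Concatenates each unit repeated its run count, with spacer fills
#' interleaved in order and the partial-repeat tail appended.
#'
#' @param d A `decomposition`.
#' @param spacer_fills Character vector of spacer sequences, one per spacer
#'   run, with matching lengths.
#' @return DNA string of length [decomposition_length()].
#' @examples
#' realize_sequence(parse_decomposition("[TCTA]9", 4))
#' @export
realize_sequence <- function(d, spacer_fills = character()) {
  stopifnot(inherits(d, "decomposition"))
  out <- character(0)
  si <- 0L
  for (r in d$runs) {
    if (r$kind == "spacer") {
      si <- si + 1L
      if (si > length(spacer_fills)) {
        stop("decomposition has ", si, " spacer(s) but only ",
             length(spacer_fills), " fill(s) were supplied", call. = FALSE)
      }
      if (nchar(spacer_fills[si]) != r$length) {
        stop("spacer fill ", si, " has length ", nchar(spacer_fills[si]),
             " but the spacer is N", r$length, call. = FALSE)
      }
      out <- c(out, spacer_fills[si])
    } else {
      out <- c(out, strrep(r$unit, r$count))
    }
  }
  paste0(paste(out, collapse = ""), d$tail)
}

#' Build the full amplicon for a locus and allele
#'
#' @param locus A `locus_definition`.
#' @param d A `decomposition` of the repeat region.
#' @return `flank5 + repeat region + flank3`.
#' @export
build_amplicon <- function(locus, d) {
  stopifnot(inherits(locus, "locus_definition"))
  paste0(locus$flank5,
         realize_sequence(d, spacer_fills = locus$spacer_fills),
         locus$flank3)
}

# instantiate a template with concrete per-block counts
.template_instantiate <- function(template, counts) {
  runs <- list()
  bi <- 0L
  for (e in template$elements) {
    if (e$kind == "spacer") {
      runs[[length(runs) + 1L]] <- list(kind = "spacer", length = e$length)
    } else {
      bi <- bi + 1L
      runs[[length(runs) + 1L]] <- list(kind = "run", unit = e$unit,
                                        count = counts[bi])
    }
  }
  decomposition(runs, period = template$period)
}

# draw one concrete decomposition for a locus: fixed blocks at reference
# count, variable blocks uniform within their configured simulation range
.draw_decomposition <- function(locus) {
  counts <- integer(0)
  vi <- 0L
  for (e in locus$template$elements) {
    if (e$kind != "block") next
    if (e$variable) {
      vi <- vi + 1L
      r <- locus$sim_counts[[vi]]
      counts <- c(counts, sample(seq.int(r[1], r[2]), 1L))
    } else {
      counts <- c(counts, e$count)
    }
  }
  .template_instantiate(locus$template, counts)
}

#' Draw a random ground-truth haplotype
#'
#' One allele per locus (two distinct alleles for multicopy loci), with
#' variable-block repeat counts drawn uniformly from each locus's
#' configured simulation range. Uses the current RNG state.
#'
#' @param panel A `ystr_panel`.
#' @param sample_id Sample identifier.
#' @param population Population label (`"AFA"`, `"CAU"` or `"HIS"`).
#' @return A `haplotype` object: per-locus list of decompositions.
#' @export
random_haplotype <- function(panel, sample_id, population = "CAU") {
  stopifnot(inherits(panel, "ystr_panel"))
  alleles <- list()
  for (locus in panel) {
    d1 <- .draw_decomposition(locus)
    if (locus$multicopy) {
      repeat {
        d2 <- .draw_decomposition(locus)
        if (!identical(render_decomposition(d2), render_decomposition(d1))) break
      }
      alleles[[locus$name]] <- list(d1, d2)
    } else {
      alleles[[locus$name]] <- list(d1)
    }
  }
  structure(list(sample_id = sample_id, population = population,
                 alleles = alleles),
            class = "haplotype")
}

#' Simulation configuration
#'
#' @param read_length Read length in bases (default 250).
#' @param coverage Read pairs simulated per allele copy: a single number
#'   applied to every locus, or `"panel"` to use each locus's configured
#'   default mean coverage.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param seed Integer seed; the same seed reproduces output byte for byte.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(read_length = 250L, coverage = 30, error_rate = 0,
                       seed = NULL) {
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]", call. = FALSE)
  }
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, seed = seed),
            class = "sim_config")
}

.coverage_for <- function(cfg, locus) {
  if (identical(cfg$coverage, "panel")) locus$mean_coverage
  else as.integer(cfg$coverage)
}

# substitute bases i.i.d. at `rate`; returns the mutated strings
.mutate_sequences <- function(strs, rate) {
  if (rate <= 0) return(strs)
  vapply(strs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in pos) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.write_fastq <- function(reads, ids, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Simulate paired-end reads for one sample
#'
#' For each allele copy of each locus, `coverage` read pairs are generated
#' from fragments that span the amplicon, padded to the read length with
#' uniformly jittered random context so both mates cover the full insert.
#' About half of the pairs are emitted with the mates swapped (the insert
#' appears reverse-complemented in R1). Substitution errors are applied
#' i.i.d. per base at the configured rate.
#'
#' @param haplotype A [random_haplotype()] object (or a manually built one).
#' @param panel A `ystr_panel`.
#' @param config A [sim_config()].
#' @param out_dir Output directory for `<sample>_R1.fastq` and
#'   `<sample>_R2.fastq`.
#' @return Invisibly, a list with `r1`, `r2` (file paths) and `manifest`,
#'   a data frame of the simulated ground truth (one row per allele copy:
#'   sample, population, locus, allele, decomposition, coverage).
#' @export
simulate_reads <- function(haplotype, panel, config = sim_config(),
                           out_dir = ".") {
  stopifnot(inherits(haplotype, "haplotype"), inherits(panel, "ystr_panel"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  L <- config$read_length
  r1 <- character(0); r2 <- character(0); ids <- character(0)
  manifest <- list()
  for (locus_name in names(haplotype$alleles)) {
    locus <- panel[[locus_name]]
    if (is.null(locus)) {
      stop("haplotype references locus '", locus_name,
           "' absent from the panel", call. = FALSE)
    }
    copies <- haplotype$alleles[[locus_name]]
    for (ci in seq_along(copies)) {
      d <- copies[[ci]]
      amp <- build_amplicon(locus, d)
      la <- nchar(amp)
      if (la > L) {
        warning("locus ", locus_name, ": amplicon (", la,
                " nt) exceeds the read length (", L,
                " nt); full-span allele calling is impossible")
      }
      nreads <- .coverage_for(config, locus)
      pad_total <- max(L - la, 0L)
      for (i in seq_len(nreads)) {
        left <- sample.int(pad_total + 1L, 1L) - 1L
        frag <- paste0(.random_dna(left), amp, .random_dna(pad_total - left))
        fwd <- if (la > L) substr(frag, 1L, L) else frag
        rev <- revcomp(if (la > L) substr(frag, la - L + 1L, la) else frag)
        if (runif(1) < 0.5) { tmp <- fwd; fwd <- rev; rev <- tmp }
        r1 <- c(r1, fwd); r2 <- c(r2, rev)
        ids <- c(ids, paste0(haplotype$sample_id, ":", locus_name, ":",
                             ci, ":", i))
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        sample_id = haplotype$sample_id,
        population = haplotype$population,
        locus = locus_name,
        allele = format(designation_from_decomposition(locus, d)),
        decomposition = render_decomposition(d),
        coverage = nreads,
        stringsAsFactors = FALSE)
    }
  }
  r1 <- .mutate_sequences(r1, config$error_rate)
  r2 <- .mutate_sequences(r2, config$error_rate)
  f1 <- file.path(out_dir, paste0(haplotype$sample_id, "_R1.fastq"))
  f2 <- file.path(out_dir, paste0(haplotype$sample_id, "_R2.fastq"))
  .write_fastq(r1, ids, f1)
  .write_fastq(r2, ids, f2)
  invisible(list(r1 = f1, r2 = f2,
                 manifest = do.call(rbind, manifest)))
}

#' Simulate a multi-sample cohort
#'
#' Draws one random haplotype per sample (by default 13 African American,
#' 12 Caucasian and 16 Hispanic males, the composition of the package's
#' demonstration cohort) and writes one FASTQ pair per sample plus a
#' combined truth manifest.
#'
#' @param panel A `ystr_panel`.
#' @param config A [sim_config()]; its `seed` governs the whole cohort.
#' @param out_dir Output directory.
#' @param n_afa,n_cau,n_his Samples per population.
#' @return Invisibly, a list with `samples` (sample sheet: sample_id,
#'   population, r1, r2) and `manifest` (combined ground truth). Both are
#'   also written to `samples.tsv` and `manifest.tsv` under `out_dir`.
#' @export
simulate_cohort <- function(panel, config = sim_config(), out_dir = ".",
                            n_afa = 13L, n_cau = 12L, n_his = 16L) {
  stopifnot(inherits(panel, "ystr_panel"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pops <- c(rep("AFA", n_afa), rep("CAU", n_cau), rep("HIS", n_his))
  idx <- c(seq_len(n_afa), seq_len(n_cau), seq_len(n_his))
  ids <- sprintf("%s%02d", pops, idx)
  per_sample_cfg <- config
  per_sample_cfg$seed <- NULL  # one seeding for the whole cohort
  samples <- list()
  manifests <- list()
  for (i in seq_along(ids)) {
    hap <- random_haplotype(panel, ids[i], pops[i])
    res <- simulate_reads(hap, panel, per_sample_cfg, out_dir = out_dir)
    samples[[i]] <- data.frame(sample_id = ids[i], population = pops[i],
                               r1 = res$r1, r2 = res$r2,
                               stringsAsFactors = FALSE)
    manifests[[i]] <- res$manifest
  }
  samples <- do.call(rbind, samples)
  manifest <- do.call(rbind, manifests)
  write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(samples = samples, manifest = manifest))
}
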