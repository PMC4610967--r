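# Classification of observed allele sequences: documented vs. repeat
# pattern variant (RPV) vs. intra-repeat SNP variant, and nominal variant
# vs. novel allele, against a known-allele catalog.

#' Explain a non-conforming sequence by a single intra-repeat SNP
#'
#' Searches for one position at which substituting a single base makes the
#' sequence parse against the template. On success, returns the
#' decomposition of the *original* sequence with the deviant unit written
#' as its own run (e.g. `[TTTC]5[TCTC]1[TTTC]17`), plus the SNP detail:
#' reference base (what the template implies), observed base, 0-based
#' index of the deviant unit copy within the decomposition, and 0-based
#' offset within the unit. If several positions work the leftmost is
#' returned; multi-substitution explanations are never attempted.
#'
#' Substitutions are only tried at offsets a valid parse could reach: a
#' rescuing position can lie at most one period beyond the deepest offset
#' any partial parse of the original sequence consumed.
#'
#' @param seq Repeat-region DNA string.
#' @param template A `motif_template`.
#' @return `list(decomposition =, snp =)` or `NULL` when no
#'   single-substitution explanation exists (including when the sequence
#'   already parses).
#' @export
snp_rescue <- function(seq, template) {
  stopifnot(inherits(template, "motif_template"))
  s <- toupper(seq)
  out0 <- decompose_repeat(s, template)
  if (out0$status == "template_match") return(NULL)
  p <- template$period
  bound <- min(nchar(s), out0$failure_position + p)
  for (i in seq_len(bound)) {
    orig <- substr(s, i, i)
    for (b in setdiff(.BASES, orig)) {
      mut <- s
      substr(mut, i, i) <- b
      out <- decompose_repeat(mut, template)
      if (out$status == "template_match") {
        res <- .deviant_run_decomposition(s, out$decomposition, i,
                                          ref_base = b, obs_base = orig)
        if (!is.null(res)) return(res)
      }
    }
  }
  NULL
}

# rewrite the matched decomposition of the mutated sequence so that the
# unit copy containing position i (1-based) becomes its own run carrying
# the original (observed) bases
.deviant_run_decomposition <- function(original_seq, d, i, ref_base, obs_base) {
  p <- d$period
  pos <- 1L
  copies_before <- 0L
  new_runs <- list()
  snp <- NULL
  for (r in d$runs) {
    span <- if (r$kind == "spacer") r$length else r$count * p
    if (is.null(snp) && r$kind == "run" && i >= pos && i < pos + span) {
      k <- (i - pos) %/% p                # copies before the deviant one
      offset <- (i - pos) %% p
      copy_start <- pos + k * p
      obs_word <- substr(original_seq, copy_start, copy_start + p - 1L)
      if (k > 0L) {
        new_runs[[length(new_runs) + 1L]] <-
          list(kind = "run", unit = r$unit, count = k)
      }
      new_runs[[length(new_runs) + 1L]] <-
        list(kind = "run", unit = obs_word, count = 1L)
      if (r$count - k - 1L > 0L) {
        new_runs[[length(new_runs) + 1L]] <-
          list(kind = "run", unit = r$unit, count = r$count - k - 1L)
      }
      snp <- list(ref_base = ref_base, obs_base = obs_base,
                  unit_index = copies_before + k, offset_in_unit = offset)
    } else {
      new_runs[[length(new_runs) + 1L]] <- r
    }
    if (r$kind == "run") copies_before <- copies_before + r$count
    pos <- pos + span
  }
  if (is.null(snp)) {
    # substitution fell in a spacer or the tail; the arrangement of unit
    # runs is unchanged and there is no deviant unit to report
    return(NULL)
  }
  list(decomposition = decomposition(new_runs, period = p, tail = d$tail),
       snp = snp)
}

#' Format a SNP detail as an "X/Y SNP" label
#'
#' Reference base first, observed base second.
#'
#' @param snp A SNP detail list as returned inside [snp_rescue()].
#' @return A string such as `"T/G SNP"`.
#' @export
format_snp <- function(snp) paste0(snp$ref_base, "/", snp$obs_base, " SNP")

#' Classify one observed allele sequence
#'
#' Pipeline: (1) decompose the sequence against the locus template; on a
#' match the sequence is *documented* if its exact decomposition is in the
#' catalog and otherwise a repeat pattern variant (RPV) — when both a pure
#' template parse and a SNP explanation would exist, the template parse
#' wins, as strand slippage is the majority mechanism of STR variation;
#' (2) on a template failure, attempt [snp_rescue()]; success makes the
#' sequence a SNP variant (or documented, if the rescued decomposition is
#' itself cataloged); (3) otherwise the sequence is unclassified and
#' surfaced for manual review. The allele designation is computed on the
#' obtained decomposition (deviant units count), and novelty is decided by
#' catalog membership of the (locus, allele) pair: a cataloged pair with a
#' different sequence is a nominal allele variant; an uncataloged pair is
#' a novel allele.
#'
#' @param locus A `locus_definition`.
#' @param seq Repeat-region DNA string.
#' @param catalog A `ystr_catalog`.
#' @return An object of class `variant_classification`: fields `status`
#'   (`documented`/`RPV`/`SNP_variant`/`unclassified`), `novelty`
#'   (`documented`/`nominal_variant`/`novel_allele`), `allele`,
#'   `decomposition` and `snp`.
#' @examples
#' \dontrun{
#' panel <- ystr_panel()
#' classify_sequence(panel[["DYS505"]], strrep("TCCT", 11), ystr_catalog())
#' }
#' @export
classify_sequence <- function(locus, seq, catalog = ystr_catalog()) {
  stopifnot(inherits(locus, "locus_definition"))
  seq <- toupper(seq)
  out <- decompose_repeat(seq, locus$template)
  snp <- NULL
  if (out$status == "template_match") {
    d <- out$decomposition
    text <- render_decomposition(d)
    status <- if (catalog_has_sequence(catalog, locus$name, text))
      "documented" else "RPV"
  } else {
    rescue <- snp_rescue(seq, locus$template)
    if (!is.null(rescue)) {
      d <- rescue$decomposition
      snp <- rescue$snp
      text <- render_decomposition(d)
      status <- if (catalog_has_sequence(catalog, locus$name, text))
        "documented" else "SNP_variant"
    } else {
      d <- NULL
      status <- "unclassified"
    }
  }
  allele <- if (!is.null(d)) {
    format(designation_from_decomposition(locus, d))
  } else {
    tryCatch(format(length_to_designation(locus, nchar(seq))),
             error = function(e) NA_character_)
  }
  novelty <- if (status == "documented") "documented"
  else if (!is.na(allele) && catalog_has_allele(catalog, locus$name, allele))
    "nominal_variant"
  else "novel_allele"
  structure(list(locus = locus$name, sequence = seq, status = status,
                 novelty = novelty, allele = allele, decomposition = d,
                 snp = snp),
            class = "variant_classification")
}

#' Variant-type label for report tables
#'
#' @param cls A `variant_classification`.
#' @return `"RPV"`, an `"X/Y SNP"` label, `"documented"` or
#'   `"unclassified"`.
#' @export
variant_type <- function(cls) {
  stopifnot(inherits(cls, "variant_classification"))
  switch(cls$status,
         RPV = "RPV",
         SNP_variant = format_snp(cls$snp),
         cls$status)
}

#' @export
print.variant_classification <- function(x, ...) {
  cat("<variant> ", x$locus, " allele ", x$allele, "\n", sep = "")
  if (!is.null(x$decomposition)) {
    cat("  decomposition: ", render_decomposition(x$decomposition), "\n",
        sep = "")
  }
  cat("  status: ", x$status,
      if (!is.null(x$snp)) paste0(" (", format_snp(x$snp), " at unit ",
                                  x$snp$unit_index, ", offset ",
                                  x$snp$offset_in_unit, ")") else "",
      "\n  novelty: ", x$novelty, "\n", sep = "")
  invisible(x)
}

#' Compile unique allele sequences across samples
#'
#' Groups allele calls by (locus, allele, sequence), aggregates the number
#' of supporting samples per population and the coverage range across
#' samples, and attaches the classification of each unique sequence.
#'
#' @param calls A data frame of [call_sample()] outputs (rows from several
#'   samples combined), with `population` labels filled in.
#' @param panel A `ystr_panel`.
#' @param catalog A `ystr_catalog`.
#' @return A data frame with one row per unique (locus, allele, sequence):
#'   locus, reference_motif, allele, observed_motif, sequence,
#'   coverage_min, coverage_max, AFA, CAU, HIS, variant_type, status,
#'   novelty; ordered by panel locus order, then allele, then motif text.
#' @export
compile_unique_sequences <- function(calls, panel = ystr_panel(),
                                     catalog = ystr_catalog()) {
  stopifnot(is.data.frame(calls), inherits(panel, "ystr_panel"))
  needed <- c("sample_id", "population", "locus", "allele", "sequence",
              "coverage")
  if (!all(needed %in% names(calls))) {
    stop("calls must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(calls)) {
    return(data.frame(locus = character(), reference_motif = character(),
                      allele = character(), observed_motif = character(),
                      sequence = character(), coverage_min = integer(),
                      coverage_max = integer(), AFA = integer(),
                      CAU = integer(), HIS = integer(),
                      variant_type = character(), status = character(),
                      novelty = character(), stringsAsFactors = FALSE))
  }
  key <- paste(calls$locus, calls$sequence, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ix) {
    g <- calls[ix, , drop = FALSE]
    if (length(unique(g$allele)) != 1L) {
      stop("inconsistent allele designations for one (locus, sequence): ",
           g$locus[1], " ", paste(unique(g$allele), collapse = "/"),
           call. = FALSE)
    }
    locus <- panel[[g$locus[1]]]
    if (is.null(locus)) {
      stop("calls reference locus '", g$locus[1],
           "' absent from the panel", call. = FALSE)
    }
    cls <- classify_sequence(locus, g$sequence[1], catalog)
    npop <- function(pop) length(unique(g$sample_id[g$population == pop]))
    data.frame(
      locus = locus$name,
      reference_motif = render_motif(locus$template),
      allele = g$allele[1],
      observed_motif = if (!is.null(cls$decomposition))
        render_decomposition(cls$decomposition) else NA_character_,
      sequence = g$sequence[1],
      coverage_min = min(g$coverage), coverage_max = max(g$coverage),
      AFA = npop("AFA"), CAU = npop("CAU"), HIS = npop("HIS"),
      variant_type = variant_type(cls),
      status = cls$status, novelty = cls$novelty,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$locus, names(panel)),
               suppressWarnings(as.numeric(out$allele)),
               out$observed_motif)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
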