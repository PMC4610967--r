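# Template-guided decomposition of a repeat-region sequence.
#
# The parse is order-preserving over the template elements: each repeat
# block consumes >= 0 whole copies of its unit (copy counts are permissive
# by default, including for nominally fixed blocks, so that e.g. the
# absence of a variable unit is not an inconsistency), and each spacer
# consumes exactly its declared number of bases with arbitrary content.
# Among multiple admissible parses the greedy leftmost-longest one is
# returned: each block takes as many copies as possible, backtracking only
# as far as needed to satisfy later blocks and spacers, which makes the
# result deterministic (equivalently, the lexicographically greatest
# per-block count vector). Up to period-1 unconsumed trailing bases are
# legal only after a terminal variable block and are recorded as a
# partial-repeat tail (microvariant support); leftover bases anywhere else
# fail the parse.

#' Decompose a repeat-region sequence against a motif template
#'
#' @param seq Repeat-region DNA string (A/C/G/T).
#' @param template A [parse_motif()] template.
#' @param strict If `TRUE`, nominally fixed blocks must match their
#'   reference copy number exactly; by default all counts are permissive.
#' @return A list with `status` (`"template_match"` or `"fails_template"`);
#'   on a match, `decomposition` (the greedy leftmost-longest parse); on a
#'   failure, `failure_position`, the 0-based offset of the first base that
#'   no partial parse could consume.
#' @examples
#' t <- parse_motif("[TCTG]3[TCTA]n", period = 4)
#' decompose_repeat(strrep("TCTA", 9), t)
#' @export
decompose_repeat <- function(seq, template, strict = FALSE) {
  stopifnot(inherits(template, "motif_template"))
  s <- toupper(seq)
  n <- nchar(s)
  if (n > 0L && !grepl("^[ACGTN]+$", s)) {
    stop("sequence contains characters outside ACGTN", call. = FALSE)
  }
  p <- template$period
  els <- template$elements
  ne <- length(els)
  last <- els[[ne]]
  tail_ok <- last$kind == "block" && last$variable

  env <- new.env(parent = emptyenv())
  env$best <- 0L
  env$result <- NULL

  count_copies <- function(pos, unit) {
    k <- 0L
    while (pos + p - 1L <= n && substr(s, pos, pos + p - 1L) == unit) {
      k <- k + 1L
      pos <- pos + p
    }
    k
  }

  rec <- function(pos, ei, counts) {
    if (!is.null(env$result)) return(invisible())
    if (pos - 1L > env$best) env$best <- pos - 1L
    if (ei > ne) {
      left <- n - pos + 1L
      if (left == 0L) {
        env$result <- list(counts = counts, tail = "")
      } else if (left < p && tail_ok) {
        env$result <- list(counts = counts, tail = substr(s, pos, n))
      }
      return(invisible())
    }
    el <- els[[ei]]
    if (el$kind == "spacer") {
      if (n - pos + 1L >= el$length) rec(pos + el$length, ei + 1L, counts)
      return(invisible())
    }
    maxc <- count_copies(pos, el$unit)
    lo <- 0L
    if (strict && !el$variable) {
      if (maxc < el$count) return(invisible())
      maxc <- el$count
      lo <- el$count
    }
    for (k in seq.int(maxc, lo)) {
      rec(pos + k * p, ei + 1L, c(counts, k))
      if (!is.null(env$result)) return(invisible())
    }
    invisible()
  }

  rec(1L, 1L, integer(0))

  if (is.null(env$result)) {
    return(list(status = "fails_template", decomposition = NULL,
                failure_position = env$best))
  }
  runs <- list()
  bi <- 0L
  for (el in els) {
    if (el$kind == "spacer") {
      runs[[length(runs) + 1L]] <- list(kind = "spacer", length = el$length)
    } else {
      bi <- bi + 1L
      runs[[length(runs) + 1L]] <- list(kind = "run", unit = el$unit,
                                        count = env$result$counts[bi])
    }
  }
  list(status = "template_match",
       decomposition = decomposition(runs, period = p, tail = env$result$tail),
       failure_position = NA_integer_)
}

#' Allele designation from a concrete decomposition
#'
#' The nominal allele is the total number of repeat units in the
#' decomposition, minus the reference copy numbers of any template blocks
#' excluded from counting by the locus definition (spacers never count);
#' a partial-repeat tail becomes the microvariant suffix. Deviant units
#' introduced by intra-repeat SNPs appear as ordinary runs and therefore
#' count toward the allele.
#'
#' @param locus A `locus_definition`.
#' @param d A `decomposition`.
#' @return An `allele_designation`.
#' @examples
#' \dontrun{
#' panel <- ystr_panel()
#' d <- parse_decomposition("[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]10", 4)
#' designation_from_decomposition(panel[["DYS389II"]], d)  # 30
#' }
#' @export
designation_from_decomposition <- function(locus, d) {
  stopifnot(inherits(locus, "locus_definition"), inherits(d, "decomposition"))
  total <- 0L
  for (r in d$runs) if (r$kind == "run") total <- total + r$count
  excluded <- .non_counted_units(locus)
  whole <- total - excluded
  if (whole < 0L) {
    stop("locus ", locus$name, ": decomposition has fewer repeat units (",
         total, ") than the ", excluded, " units of its non-counted blocks",
         call. = FALSE)
  }
  designation(whole, nchar(d$tail))
}

# total reference repeat units in blocks excluded from the allele count
.non_counted_units <- function(locus) {
  blocks <- Filter(function(e) e$kind == "block", locus$template$elements)
  excl <- 0L
  for (i in seq_along(blocks)) {
    if (!locus$counted_blocks[i]) {
      if (blocks[[i]]$variable) {
        stop("locus ", locus$name,
             ": non-counted block ", i, " has a symbolic reference count",
             call. = FALSE)
      }
      excl <- excl + blocks[[i]]$count
    }
  }
  excl
}

# total fixed bases excluded from length-based designation: spacers plus
# non-counted blocks at their reference copy numbers
.non_counted_bases <- function(locus) {
  sp <- 0L
  for (e in locus$template$elements) {
    if (e$kind == "spacer") sp <- sp + e$length
  }
  sp + .non_counted_units(locus) * locus$template$period
}

#' Length-based allele designation
#'
#' The nominal allele ascertainable from sequence length alone: the
#' repeat-region length minus the locus's fixed non-counted bases (spacers
#' plus non-counted blocks at reference copy number), divided by the
#' period; the remainder becomes the microvariant suffix.
#'
#' @param locus A `locus_definition`.
#' @param region_length Repeat-region length in bases.
#' @return An `allele_designation`.
#' @export
length_to_designation <- function(locus, region_length) {
  stopifnot(inherits(locus, "locus_definition"))
  region_length <- as.integer(region_length)
  adj <- region_length - .non_counted_bases(locus)
  if (adj < 0L) {
    stop("locus ", locus$name, ": region length ", region_length,
         " is shorter than the locus's fixed non-counted bases", call. = FALSE)
  }
  p <- locus$template$period
  designation(adj %/% p, adj %% p)
}
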