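# Bracket dialect
# ---------------
# Repeat-region grammars and concrete decompositions share one textual
# dialect:
#   [UNIT]k     a block of k copies of UNIT (k integer, or n/p/q/r for a
#               variable block in a motif template)
#   N<len>      a fixed-length non-repeat spacer of <len> bases
#   +BASES      a terminal partial repeat shorter than one period
#               (microvariant tail; decompositions only)
# Whitespace between tokens is ignored on input. The canonical rendering
# has no space inside or between blocks and a single space on either side
# of a spacer token, e.g. "[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]10".

.SYMBOLIC_COUNTS <- c("n", "p", "q", "r")

.tokenize_bracket_text <- function(text) {
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) return(list(tokens = list(), text = s))
  pat <- "\\[([ACGT]+)\\]([0-9]+|[npqr])|N([0-9]+)|\\+([ACGT]+)$"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    stop("cannot parse bracket notation near '", substr(s, 1, 12), "'",
         call. = FALSE)
  }
  ends <- m + attr(m, "match.length") - 1L
  # tokens must tile the string with no gaps
  expect_start <- 1L
  for (i in seq_along(m)) {
    if (m[i] != expect_start) {
      bad <- substr(s, expect_start, m[i] - 1L)
      stop("unrecognized token '", bad, "' in '", text, "'", call. = FALSE)
    }
    expect_start <- ends[i] + 1L
  }
  if (expect_start != nchar(s) + 1L) {
    stop("unrecognized token '", substr(s, expect_start, nchar(s)),
         "' in '", text, "'", call. = FALSE)
  }
  toks <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]
  parsed <- lapply(toks, function(t) {
    if (startsWith(t, "[")) {
      unit <- sub("^\\[([ACGT]+)\\].*$", "\\1", t)
      cnt <- sub("^\\[[ACGT]+\\]", "", t)
      if (cnt %in% .SYMBOLIC_COUNTS) {
        list(kind = "block", unit = unit, count = NA_integer_,
             variable = TRUE, symbol = cnt)
      } else {
        list(kind = "block", unit = unit, count = as.integer(cnt),
             variable = FALSE, symbol = NULL)
      }
    } else if (startsWith(t, "N")) {
      list(kind = "spacer", length = as.integer(sub("^N", "", t)))
    } else {
      list(kind = "tail", bases = sub("^\\+", "", t))
    }
  })
  list(tokens = parsed, text = s)
}

.check_unit <- function(unit, period, context) {
  if (!grepl("^[ACGT]+$", unit)) {
    stop(context, ": repeat unit '", unit, "' contains non-ACGT characters",
         call. = FALSE)
  }
  if (nchar(unit) < 3L || nchar(unit) > 5L) {
    stop(context, ": repeat unit '", unit, "' must be 3-5 bases long",
         call. = FALSE)
  }
  if (nchar(unit) != period) {
    stop(context, ": repeat unit '", unit, "' has length ", nchar(unit),
         " but the locus period is ", period, call. = FALSE)
  }
  invisible(unit)
}

#' Parse a repeat-motif template from bracket notation
#'
#' A motif template describes the repeat grammar of an STR locus as an
#' ordered list of repeat blocks (fixed or variable copy number) and
#' fixed-length spacers, e.g. `"[TCTG]n[TCTA]p N48 [TCTG]3[TCTA]q"`.
#' Symbolic counts (`n`, `p`, `q`, `r`) mark variable blocks.
#'
#' @param text Motif string in bracket notation.
#' @param period Repeat unit length (3-5 bases); all blocks must share it.
#' @return An object of class `motif_template` with elements `elements`
#'   (list of blocks and spacers), `period` and `unit_alphabet`.
#' @examples
#' parse_motif("[CTT]n", period = 3)
#' parse_motif("[TCTG]n[TCTA]p N48 [TCTG]3[TCTA]q", period = 4)
#' @export
parse_motif <- function(text, period) {
  period <- as.integer(period)
  tk <- .tokenize_bracket_text(text)
  if (!length(tk$tokens)) stop("empty motif text", call. = FALSE)
  elements <- list()
  for (t in tk$tokens) {
    if (t$kind == "tail") {
      stop("partial-repeat tails ('+", t$bases,
           "') are not allowed in motif templates", call. = FALSE)
    }
    if (t$kind == "block") .check_unit(t$unit, period, paste0("motif '", text, "'"))
    if (t$kind == "spacer" && t$length < 1L) {
      stop("spacer length must be positive in '", text, "'", call. = FALSE)
    }
    elements[[length(elements) + 1L]] <- t
  }
  blocks <- Filter(function(e) e$kind == "block", elements)
  if (!length(blocks)) stop("motif '", text, "' has no repeat blocks", call. = FALSE)
  if (!any(vapply(blocks, `[[`, logical(1), "variable"))) {
    stop("motif '", text, "' has no variable block", call. = FALSE)
  }
  structure(
    list(elements = elements, period = period,
         unit_alphabet = unique(vapply(blocks, `[[`, character(1), "unit"))),
    class = "motif_template")
}

#' Render a motif template in canonical bracket notation
#'
#' @param template A `motif_template`.
#' @return Canonical motif string.
#' @export
render_motif <- function(template) {
  stopifnot(inherits(template, "motif_template"))
  parts <- vapply(template$elements, function(e) {
    if (e$kind == "spacer") paste0(" N", e$length, " ")
    else if (e$variable) paste0("[", e$unit, "]", e$symbol)
    else paste0("[", e$unit, "]", e$count)
  }, character(1))
  trimws(gsub("  +", " ", paste(parts, collapse = "")))
}

#' Construct a concrete repeat decomposition
#'
#' A decomposition is a run-length parse of one repeat-region sequence:
#' maximal runs of repeat units, fixed-length spacer fills, and an optional
#' terminal partial repeat shorter than one period (a microvariant tail).
#' Adjacent runs with the same unit are merged so runs are always maximal.
#'
#' @param runs List of runs; each is `list(kind = "run", unit =, count =)`
#'   or `list(kind = "spacer", length =)`.
#' @param period Repeat unit length in bases.
#' @param tail Terminal partial-repeat bases (default none).
#' @return An object of class `decomposition`.
#' @export
decomposition <- function(runs, period, tail = "") {
  period <- as.integer(period)
  merged <- list()
  for (r in runs) {
    if (r$kind == "run") {
      .check_unit(r$unit, period, "decomposition")
      r$count <- as.integer(r$count)
      if (r$count < 0L) stop("run count must be non-negative", call. = FALSE)
      if (r$count == 0L) next
      last <- if (length(merged)) merged[[length(merged)]] else NULL
      if (!is.null(last) && last$kind == "run" && last$unit == r$unit) {
        merged[[length(merged)]]$count <- last$count + r$count
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  if (nzchar(tail) && nchar(tail) >= period) {
    stop("partial-repeat tail '", tail, "' must be shorter than one period",
         call. = FALSE)
  }
  structure(list(runs = merged, period = period, tail = tail),
            class = "decomposition")
}

#' Parse a concrete decomposition from bracket notation
#'
#' Unlike a motif template, every count must be a concrete integer; an
#' optional trailing `+BASES` token records a terminal partial repeat
#' (e.g. `"[GAAA]13+GA"` for a x.2 microvariant).
#'
#' @inheritParams parse_motif
#' @return An object of class `decomposition`.
#' @examples
#' parse_decomposition("[CGAT]1[AGAT]12", period = 4)
#' @export
parse_decomposition <- function(text, period) {
  period <- as.integer(period)
  tk <- .tokenize_bracket_text(text)
  runs <- list()
  tail <- ""
  for (i in seq_along(tk$tokens)) {
    t <- tk$tokens[[i]]
    if (t$kind == "block") {
      if (t$variable) {
        stop("decomposition '", text, "' contains symbolic count '",
             t$symbol, "'; counts must be concrete integers", call. = FALSE)
      }
      runs[[length(runs) + 1L]] <- list(kind = "run", unit = t$unit,
                                        count = t$count)
    } else if (t$kind == "spacer") {
      runs[[length(runs) + 1L]] <- list(kind = "spacer", length = t$length)
    } else {
      if (i != length(tk$tokens)) {
        stop("partial-repeat tail must be the final token in '", text, "'",
             call. = FALSE)
      }
      tail <- t$bases
    }
  }
  decomposition(runs, period = period, tail = tail)
}

#' Render a decomposition in canonical bracket notation
#'
#' @param d A `decomposition`.
#' @return Canonical decomposition string; `render_decomposition` and
#'   [parse_decomposition()] are mutually inverse on canonical strings.
#' @export
render_decomposition <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  parts <- vapply(d$runs, function(r) {
    if (r$kind == "spacer") paste0(" N", r$length, " ")
    else paste0("[", r$unit, "]", r$count)
  }, character(1))
  out <- trimws(gsub("  +", " ", paste(parts, collapse = "")))
  if (nzchar(d$tail)) out <- paste0(out, "+", d$tail)
  out
}

#' Total base length realized by a decomposition
#'
#' Sum of `count * period` over unit runs, plus spacer lengths, plus the
#' partial-repeat tail.
#'
#' @param d A `decomposition`.
#' @return Length in bases.
#' @export
decomposition_length <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  n <- 0L
  for (r in d$runs) {
    n <- n + if (r$kind == "spacer") r$length else r$count * d$period
  }
  n + nchar(d$tail)
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition> ", render_decomposition(x),
      "  (", decomposition_length(x), " nt)\n", sep = "")
  invisible(x)
}

#' @export
print.motif_template <- function(x, ...) {
  cat("<motif_template> ", render_motif(x), "  (period ", x$period, ")\n",
      sep = "")
  invisible(x)
}

#' Allele designation (nominal repeat count)
#'
#' The nominal name of an STR allele: a whole repeat count plus a residual
#' partial-repeat length in bases, rendered "13" when the residual is zero
#' and "13.2"-style for microvariants.
#'
#' @param whole Non-negative integer repeat count.
#' @param partial Residual bases, `0 <= partial < period`.
#' @return An object of class `allele_designation`.
#' @export
designation <- function(whole, partial = 0L) {
  whole <- as.integer(whole)
  partial <- as.integer(partial)
  if (is.na(whole) || whole < 0L) stop("whole repeat count must be >= 0", call. = FALSE)
  if (is.na(partial) || partial < 0L) stop("partial length must be >= 0", call. = FALSE)
  structure(list(whole = whole, partial = partial), class = "allele_designation")
}

#' @method format allele_designation
#' @export
format.allele_designation <- function(x, ...) {
  if (x$partial > 0L) paste0(x$whole, ".", x$partial) else as.character(x$whole)
}

#' @export
as.character.allele_designation <- function(x, ...) format(x)

#' @export
print.allele_designation <- function(x, ...) {
  cat("<allele> ", format(x), "\n", sep = "")
  invisible(x)
}
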