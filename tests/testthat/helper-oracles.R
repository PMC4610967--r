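# Independent oracles used to cross-check the template parser and the
# single-substitution classifier. Both are deliberately different
# algorithms from the implementation: a reachable-position-set dynamic
# program for acceptance, and plain descending-lexicographic enumeration
# for the greedy parse.

# Does `seq` admit ANY order-preserving parse of `template`?
# DP over the set of consumed-base counts reachable after each element.
oracle_accepts <- function(seq, template) {
  s <- toupper(seq)
  n <- nchar(s)
  p <- template$period
  reach <- 0L
  for (el in template$elements) {
    if (el$kind == "spacer") {
      reach <- reach[reach + el$length <= n] + el$length
    } else {
      nxt <- integer(0)
      for (pos0 in reach) {
        pos <- pos0 + 1L
        k <- 0L
        nxt <- c(nxt, pos0)
        while (pos + p - 1L <= n && substr(s, pos, pos + p - 1L) == el$unit) {
          k <- k + 1L
          nxt <- c(nxt, pos0 + k * p)
          pos <- pos + p
        }
      }
      reach <- unique(nxt)
    }
    if (!length(reach)) return(FALSE)
  }
  last <- template$elements[[length(template$elements)]]
  tail_ok <- last$kind == "block" && last$variable
  any(reach == n) || (tail_ok && any(n - reach > 0L & n - reach < p))
}

# First (descending-lexicographic) block-count assignment whose
# realization equals `seq`; returns the canonical decomposition text or
# NULL. Spacer-free templates only. Used on small random templates.
oracle_greedy_parse <- function(seq, template) {
  s <- toupper(seq)
  n <- nchar(s)
  p <- template$period
  blocks <- Filter(function(e) e$kind == "block", template$elements)
  stopifnot(length(blocks) == length(template$elements))
  nb <- length(blocks)
  maxc <- n %/% p
  last_var <- blocks[[nb]]$variable
  grid <- do.call(expand.grid, rev(rep(list(seq.int(maxc, 0L)), nb)))
  grid <- grid[, rev(seq_len(nb)), drop = FALSE]  # lexicographic on block 1 first
  for (r in seq_len(nrow(grid))) {
    counts <- as.integer(grid[r, ])
    body_len <- sum(counts) * p
    tail_len <- n - body_len
    if (tail_len < 0L || tail_len >= p) next
    if (tail_len > 0L && !last_var) next
    realized <- paste0(
      paste(vapply(seq_len(nb),
                   function(i) strrep(blocks[[i]]$unit, counts[i]),
                   character(1)), collapse = ""),
      substr(s, body_len + 1L, n))
    if (realized != s) next
    runs <- lapply(seq_len(nb), function(i)
      list(kind = "run", unit = blocks[[i]]$unit, count = counts[i]))
    d <- decomposition(runs, period = p,
                       tail = substr(s, body_len + 1L, n))
    return(render_decomposition(d))
  }
  NULL
}

# Random spacer-free template with <= 3 blocks over a small unit pool,
# plus a random concrete realization of it.
random_template_case <- function() {
  p <- sample(3:4, 1)
  pool <- if (p == 3) c("CTT", "TCT", "CCT", "ACT") else
    c("TCTA", "TCTG", "TGTA", "GATA")
  nb <- sample(1:3, 1)
  units <- sample(pool, nb)
  counts <- sample(0:6, nb, replace = TRUE)
  variable <- sample(c(TRUE, FALSE), nb, replace = TRUE)
  variable[sample.int(nb, 1)] <- TRUE  # at least one variable block
  motif <- paste(vapply(seq_len(nb), function(i) {
    paste0("[", units[i], "]",
           if (variable[i]) sample(c("n", "p", "q"), 1) else
             as.character(max(counts[i], 1L)))
  }, character(1)), collapse = "")
  template <- parse_motif(motif, p)
  seq <- paste(vapply(seq_len(nb), function(i) strrep(units[i], counts[i]),
                      character(1)), collapse = "")
  list(template = template, seq = seq)
}

test_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ystr_panel()
    cache
  }
})

test_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ystr_catalog()
    cache
  }
})

# realize one observed-variant table row into its repeat-region sequence
realize_variant_row <- function(row, panel = test_panel()) {
  locus <- panel[[row$locus]]
  d <- parse_decomposition(row$observed_motif, locus$template$period)
  realize_sequence(d, spacer_fills = locus$spacer_fills)
}
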