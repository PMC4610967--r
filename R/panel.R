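# Panel configuration: the 28 Y-STR locus definitions (repeat grammar,
# flank anchors, counted-block rule) and the known-allele catalog.

#' Names of the 28 Y-STR loci in the bundled panel
#' @export
PANEL_LOCI <- c(
  "DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
  "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS449", "DYS456",
  "DYS458", "DYS460", "DYS481", "DYS505", "DYS518", "DYS522", "DYS533",
  "DYS549", "DYS570", "DYS576", "DYS612", "DYS635", "DYS643", "GATA-H4")

#' Construct a single Y-STR locus definition
#'
#' @param name Locus name.
#' @param motif Reference repeat motif in bracket notation (see
#'   [parse_motif()]).
#' @param period Repeat unit length in bases (3-5).
#' @param flank5,flank3 Flanking anchor sequences (>= 12 nt each) used to
#'   locate and excise the repeat region from reads.
#' @param counted_blocks `"all"`, or a logical vector over the template's
#'   repeat blocks marking which contribute to the allele designation.
#' @param multicopy `TRUE` for loci present in two copies (DYS385).
#' @param spacer_fills Fixed spacer sequences, one per `N<len>` element of
#'   the motif, used when realizing sequences; content is otherwise opaque.
#' @param sim_counts List of `c(lo, hi)` ranges, one per variable block,
#'   from which the read simulator draws repeat counts.
#' @param mean_coverage Default simulated read-pair count for this locus.
#' @return An object of class `locus_definition`.
#' @export
locus_definition <- function(name, motif, period, flank5, flank3,
                             counted_blocks = "all", multicopy = FALSE,
                             spacer_fills = character(),
                             sim_counts = NULL, mean_coverage = 100L) {
  template <- parse_motif(motif, period)
  for (fl in c(flank5, flank3)) {
    if (!grepl("^[ACGT]+$", fl)) {
      stop("locus ", name, ": flank anchor '", fl,
           "' contains non-ACGT characters", call. = FALSE)
    }
    if (nchar(fl) < 12L) {
      stop("locus ", name, ": flank anchor '", fl,
           "' is shorter than 12 nt", call. = FALSE)
    }
  }
  blocks <- Filter(function(e) e$kind == "block", template$elements)
  if (identical(counted_blocks, "all")) {
    counted_blocks <- rep(TRUE, length(blocks))
  }
  counted_blocks <- as.logical(counted_blocks)
  if (length(counted_blocks) != length(blocks)) {
    stop("locus ", name, ": counted_blocks has length ",
         length(counted_blocks), " but the motif has ", length(blocks),
         " repeat blocks", call. = FALSE)
  }
  if (!any(counted_blocks)) {
    stop("locus ", name, ": at least one block must be counted", call. = FALSE)
  }
  spacers <- Filter(function(e) e$kind == "spacer", template$elements)
  spacer_fills <- as.character(spacer_fills)
  if (length(spacer_fills) != length(spacers)) {
    stop("locus ", name, ": ", length(spacers), " spacer(s) in the motif but ",
         length(spacer_fills), " spacer fill(s) supplied", call. = FALSE)
  }
  for (i in seq_along(spacers)) {
    if (nchar(spacer_fills[i]) != spacers[[i]]$length) {
      stop("locus ", name, ": spacer fill ", i, " has length ",
           nchar(spacer_fills[i]), " but the motif declares N",
           spacers[[i]]$length, call. = FALSE)
    }
  }
  nvar <- sum(vapply(blocks, `[[`, logical(1), "variable"))
  if (is.null(sim_counts)) {
    sim_counts <- rep(list(c(8L, 15L)), nvar)
  }
  if (length(sim_counts) != nvar) {
    stop("locus ", name, ": sim_counts must give one range per variable block",
         call. = FALSE)
  }
  structure(
    list(name = name, template = template, flank5 = flank5, flank3 = flank3,
         counted_blocks = counted_blocks, multicopy = isTRUE(multicopy),
         spacer_fills = spacer_fills,
         sim_counts = lapply(sim_counts, as.integer),
         mean_coverage = as.integer(mean_coverage)),
    class = "locus_definition")
}

#' @export
print.locus_definition <- function(x, ...) {
  cat("<locus> ", x$name, "  ", render_motif(x$template),
      if (x$multicopy) "  (multicopy)" else "", "\n", sep = "")
  invisible(x)
}

#' Load a Y-STR panel configuration
#'
#' Reads a YAML panel file (one mapping per locus: name, period, motif,
#' flank anchors, optional counted-block mask, spacer fills and simulation
#' ranges) and validates it against the fixed 28-locus panel list.
#'
#' @param path Path to a panel YAML file; the default is the configuration
#'   bundled with the package.
#' @param complete If `TRUE` (default), require exactly the 28 panel loci;
#'   missing or unknown names are an error. Set `FALSE` to load partial
#'   panels for experimentation.
#' @return A named list of `locus_definition` objects, class `ystr_panel`.
#' @export
load_panel <- function(path = system.file("extdata", "panel.yaml",
                                          package = "ystrseq"),
                       complete = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci)) stop("panel file has no 'loci' list", call. = FALSE)
  loci <- list()
  for (entry in cfg$loci) {
    for (fld in c("name", "period", "motif", "flank5", "flank3")) {
      if (is.null(entry[[fld]])) {
        stop("panel entry ", entry$name %||% "<unnamed>",
             ": missing field '", fld, "'", call. = FALSE)
      }
    }
    if (complete && !(entry$name %in% PANEL_LOCI)) {
      stop("unknown locus name '", entry$name, "' in panel file", call. = FALSE)
    }
    if (entry$name %in% names(loci)) {
      stop("duplicate locus '", entry$name, "' in panel file", call. = FALSE)
    }
    cb <- entry$counted_blocks %||% "all"
    if (!identical(cb, "all")) cb <- as.logical(unlist(cb))
    loci[[entry$name]] <- locus_definition(
      name = entry$name, motif = entry$motif, period = entry$period,
      flank5 = entry$flank5, flank3 = entry$flank3, counted_blocks = cb,
      multicopy = entry$multicopy %||% FALSE,
      spacer_fills = unlist(entry$spacer_fills) %||% character(),
      sim_counts = entry$sim_counts,
      mean_coverage = entry$mean_coverage %||% 100L)
  }
  if (complete) {
    missing <- setdiff(PANEL_LOCI, names(loci))
    if (length(missing)) {
      stop("panel file is missing ", length(missing), " locus/loci: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    loci <- loci[PANEL_LOCI]
  }
  structure(loci, class = "ystr_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
`[.ystr_panel` <- function(x, i) {
  structure(NextMethod(), class = "ystr_panel")
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat("<ystr_panel> ", length(x), " loci: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The bundled 28-locus Y-STR panel
#'
#' @return A `ystr_panel` loaded from the package's default configuration.
#' @export
ystr_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel()
    cache
  }
})

#' Load a known-allele catalog
#'
#' The catalog is a tab-separated table with columns `locus`, `allele`,
#' `decomposition`, `source` and optionally `snp` (an `X/Y` label for
#' documented sequences that carry an intra-repeat SNP and therefore do
#' not parse against the reference motif). Every row is validated against
#' the panel: the decomposition must parse, its designation must equal the
#' stated allele, and — unless the SNP flag is set — its realized sequence
#' must be consistent with the locus template.
#'
#' @param path Path to a catalog TSV; the default is the fixture catalog
#'   bundled with the package.
#' @param panel A `ystr_panel` used for validation.
#' @return A data frame of class `ystr_catalog` with canonicalized
#'   decomposition text.
#' @export
load_catalog <- function(path = system.file("extdata", "catalog.tsv",
                                            package = "ystrseq"),
                         panel = ystr_panel()) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("locus", "allele", "decomposition", "source") %in% names(df))) {
    stop("catalog must have columns locus/allele/decomposition/source",
         call. = FALSE)
  }
  if (is.null(df$snp)) df$snp <- rep("", nrow(df))
  df$snp[is.na(df$snp)] <- ""
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      loc <- df$locus[i]
      if (!(loc %in% names(panel))) {
        stop("catalog line ", i + 1L, ": unknown locus '", loc, "'",
             call. = FALSE)
      }
      locus <- panel[[loc]]
      d <- tryCatch(
        parse_decomposition(df$decomposition[i], locus$template$period),
        error = function(e) {
          stop("catalog line ", i + 1L, " (", loc, "): ",
               conditionMessage(e), call. = FALSE)
        })
      df$decomposition[i] <- render_decomposition(d)
      des <- format(designation_from_decomposition(locus, d))
      if (des != df$allele[i]) {
        stop("catalog line ", i + 1L, " (", loc, "): decomposition yields ",
             "allele ", des, " but the row states ", df$allele[i],
             call. = FALSE)
      }
      if (!nzchar(df$snp[i])) {
        seq <- realize_sequence(d, spacer_fills = locus$spacer_fills)
        out <- decompose_repeat(seq, locus$template)
        if (out$status != "template_match") {
          stop("catalog line ", i + 1L, " (", loc, "): decomposition is ",
               "inconsistent with the locus motif and carries no SNP flag",
               call. = FALSE)
        }
      }
    }
    dup <- duplicated(df[c("locus", "allele", "decomposition")])
    if (any(dup)) {
      warning("catalog: dropped ", sum(dup), " duplicate row(s)")
      df <- df[!dup, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("ystr_catalog", "data.frame"))
}

#' The bundled known-allele catalog fixture
#'
#' @return A `ystr_catalog`.
#' @export
ystr_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_catalog()
    cache
  }
})

# does the catalog document this exact (locus, decomposition text)?
catalog_has_sequence <- function(catalog, locus_name, decomposition_text) {
  any(catalog$locus == locus_name & catalog$decomposition == decomposition_text)
}

# does the catalog document any sequence for this (locus, allele)?
catalog_has_allele <- function(catalog, locus_name, allele_text) {
  any(catalog$locus == locus_name & catalog$allele == allele_text)
}
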