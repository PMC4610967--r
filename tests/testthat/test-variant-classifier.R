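# SNP rescue, documented/RPV/SNP classification, unique-sequence compiler.

test_that("a leading deviant unit is rescued as a single SNP", {
  l481 <- test_panel()[["DYS481"]]
  res <- snp_rescue(paste0("CTG", strrep("CTT", 24)), l481$template)
  expect_identical(render_decomposition(res$decomposition), "[CTG]1[CTT]24")
  expect_identical(format_snp(res$snp), "T/G SNP")
  expect_identical(res$snp$unit_index, 0L)
  expect_identical(res$snp$offset_in_unit, 2L)
})

test_that("an interior deviant unit splits its run", {
  l570 <- test_panel()[["DYS570"]]
  seq <- paste0(strrep("TTTC", 5), "TCTC", strrep("TTTC", 17))
  res <- snp_rescue(seq, l570$template)
  expect_identical(render_decomposition(res$decomposition),
                   "[TTTC]5[TCTC]1[TTTC]17")
  expect_identical(format_snp(res$snp), "T/C SNP")
  expect_identical(res$snp$unit_index, 5L)
  expect_identical(res$snp$offset_in_unit, 1L)
})

test_that("an interrupting unit from the template alphabet is still rescued", {
  # the CCT interrupting the [TCT]n block is a template word, but no parse
  # places a CCT run there; a single T/C substitution explains it
  l612 <- test_panel()[["DYS612"]]
  seq <- realize_sequence(parse_decomposition(
    "[CCT]5[CTT]1[TCT]4[CCT]1[TCT]17[CCT]1[TCT]12", 3))
  res <- snp_rescue(seq, l612$template)
  expect_identical(render_decomposition(res$decomposition),
                   "[CCT]5[CTT]1[TCT]4[CCT]1[TCT]17[CCT]1[TCT]12")
  expect_identical(format_snp(res$snp), "T/C SNP")
})

test_that("the classic two-block illustration rescues as a C/A SNP", {
  t <- parse_motif("[TCTA]n[TCTG]p", 4)
  seq <- paste0(strrep("TCTA", 5), "TATA", strrep("TCTG", 11))
  res <- snp_rescue(seq, t)
  expect_identical(render_decomposition(res$decomposition),
                   "[TCTA]5[TATA]1[TCTG]11")
  expect_identical(format_snp(res$snp), "C/A SNP")
})

test_that("sequences that already parse, or need two changes, are not rescued", {
  l481 <- test_panel()[["DYS481"]]
  expect_null(snp_rescue(strrep("CTT", 20), l481$template))
  two <- paste0("CTG", strrep("CTT", 10), "CTG", strrep("CTT", 10))
  expect_null(snp_rescue(two, l481$template))
})

test_that("classification separates documented, RPV and SNP variants", {
  panel <- test_panel()
  cg <- test_catalog()
  # catalog sequence fed back verbatim is documented/documented
  doc <- classify_sequence(panel[["DYS389I"]],
                           realize_sequence(parse_decomposition(
                             "[TCTG]3[TCTA]6", 4)), cg)
  expect_identical(doc$status, "documented")
  expect_identical(doc$novelty, "documented")
  # a cataloged SNP-carrying sequence is also documented
  doc2 <- classify_sequence(panel[["DYS481"]],
                            paste0("CTG", strrep("CTT", 20)), cg)
  expect_identical(doc2$status, "documented")
  # allele 9 as pure TCTA: an RPV of a documented allele
  rpv <- classify_sequence(panel[["DYS389I"]], strrep("TCTA", 9), cg)
  expect_identical(rpv$status, "RPV")
  expect_identical(rpv$novelty, "nominal_variant")
  expect_identical(rpv$allele, "9")
  # an allele with no catalog entry at all: novel
  novel <- classify_sequence(panel[["DYS505"]], strrep("TCCT", 11), cg)
  expect_identical(novel$status, "RPV")
  expect_identical(novel$novelty, "novel_allele")
  # SNP variant of a documented allele
  snp <- classify_sequence(panel[["DYS481"]],
                           paste0("CTG", strrep("CTT", 24)), cg)
  expect_identical(snp$status, "SNP_variant")
  expect_identical(variant_type(snp), "T/G SNP")
  expect_identical(snp$allele, "25")
  expect_identical(snp$novelty, "nominal_variant")
  # unclassifiable: two substitutions away from the motif
  uncl <- classify_sequence(panel[["DYS481"]],
                            paste0("CTG", strrep("CTT", 10), "CTG",
                                   strrep("CTT", 10)), cg)
  expect_identical(uncl$status, "unclassified")
})

test_that("a pure template parse wins over a SNP explanation", {
  # TGTA can arise from TCTA by one substitution, but DYS635 admits TGTA
  # runs in place; the template parse must be preferred (RPV, not SNP)
  l635 <- test_panel()[["DYS635"]]
  seq <- realize_sequence(parse_decomposition(
    "[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]3[TCTA]8", 4))
  cls <- classify_sequence(l635, seq, test_catalog())
  expect_identical(cls$status, "RPV")
})

test_that("every single-base mutant of a parsable catalog sequence is classified", {
  # exhaustive single-substitution sweep over catalog sequences <= 120 nt,
  # cross-checked against an independent reachable-set acceptor
  panel <- test_panel()
  cg <- test_catalog()
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (i in seq_len(nrow(cg))) {
    locus <- panel[[cg$locus[i]]]
    d <- parse_decomposition(cg$decomposition[i], locus$template$period)
    if (nzchar(cg$snp[i])) next        # start from motif-consistent sequences
    seq <- realize_sequence(d, locus$spacer_fills)
    if (nchar(seq) > 120L || nchar(seq) == 0L) next
    has_spacer <- any(vapply(d$runs, function(r) r$kind == "spacer",
                             logical(1)))
    if (has_spacer) next               # oracle below is spacer-free
    for (pos in seq_len(nchar(seq))) {
      for (b in setdiff(bases, substr(seq, pos, pos))) {
        mut <- seq
        substr(mut, pos, pos) <- b
        cls <- classify_sequence(locus, mut, cg)
        expect_false(cls$status == "unclassified",
                     label = paste(locus$name, "pos", pos, "->", b))
        parses <- oracle_accepts(mut, locus$template)
        if (parses) {
          expect_true(cls$status %in% c("documented", "RPV"),
                      label = paste(locus$name, "pos", pos, "->", b))
        } else {
          expect_identical(cls$status, "SNP_variant",
                           label = paste(locus$name, "pos", pos, "->", b))
          # the reported SNP must revert the mutant to a parsable sequence
          fix <- cls$sequence
          idx <- 0L
          off <- 0L
          for (r in cls$decomposition$runs) {
            if (r$kind == "spacer") { off <- off + r$length; next }
            if (idx + r$count > cls$snp$unit_index) {
              off <- off + (cls$snp$unit_index - idx) * locus$template$period
              break
            }
            idx <- idx + r$count
            off <- off + r$count * locus$template$period
          }
          fixpos <- off + cls$snp$offset_in_unit + 1L
          substr(fix, fixpos, fixpos) <- cls$snp$ref_base
          expect_true(oracle_accepts(fix, locus$template),
                      label = paste(locus$name, "revert pos", fixpos))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 3000L)
})

test_that("unique sequences aggregate samples, populations and coverage", {
  panel <- test_panel()
  cg <- test_catalog()
  seq390 <- realize_sequence(parse_decomposition(
    "[TCTG]8[TCTA]8[TCTG]1[TCTA]4", 4))
  calls <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(sample_id = paste0("AFA", i), population = "AFA",
               locus = "DYS390", allele = "21", sequence = seq390,
               coverage = c(15L, 60L)[1 + (i %% 2)],
               stringsAsFactors = FALSE)
  }))
  rec <- compile_unique_sequences(calls, panel, cg)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$AFA, 8L)
  expect_identical(rec$CAU, 0L)
  expect_identical(rec$HIS, 0L)
  expect_identical(rec$coverage_min, 15L)
  expect_identical(rec$coverage_max, 60L)
  expect_identical(rec$variant_type, "RPV")
  expect_identical(rec$observed_motif, "[TCTG]8[TCTA]8[TCTG]1[TCTA]4")
})

test_that("conflicting designations for one sequence are an error", {
  calls <- data.frame(
    sample_id = c("A", "B"), population = c("AFA", "CAU"),
    locus = "DYS391", allele = c("10", "11"),
    sequence = strrep("TCTA", 10), coverage = 9L,
    stringsAsFactors = FALSE)
  expect_error(compile_unique_sequences(calls, test_panel(), test_catalog()),
               "inconsistent")
})

test_that("one sample yields total count one per record", {
  calls <- data.frame(
    sample_id = "HIS01", population = "HIS", locus = "DYS533",
    allele = "9", sequence = strrep("ATCT", 9), coverage = 113L,
    stringsAsFactors = FALSE)
  rec <- compile_unique_sequences(calls, test_panel(), test_catalog())
  expect_identical(rec$AFA + rec$CAU + rec$HIS, 1L)
  expect_identical(rec$novelty, "novel_allele")
})
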