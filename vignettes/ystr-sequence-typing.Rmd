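---
title: "Sequence-based Y-STR typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based Y-STR typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short tandem repeats on the Y chromosome (Y-STRs) are haploid, paternally
inherited markers used throughout forensic genetics and lineage studies.
Conventional typing by capillary electrophoresis reports only the *nominal
allele* — the repeat-count equivalent of the amplicon length. Massively
parallel sequencing keeps the underlying nucleotide sequence, so two
alleles of identical length can still be distinguished when they differ in
the internal arrangement of repeat units or carry a single-base change
inside a repeat. `ystrseq` implements the full analytic chain needed to
exploit that extra resolution:

1. **flank-anchored allele calling** — find a locus's conserved 5′ and 3′
   anchor sequences in each raw read (either orientation), excise the
   intervening repeat region, genotype it by length, and retain its
   sequence;
2. **unique-sequence compilation** — tally identical extracted sequences
   per locus across reads and samples, applying a minimum coverage floor
   of 5 supporting reads per reported sequence;
3. **motif decomposition** — parse each repeat region against the locus's
   repeat-motif grammar into bracketed run-length notation such as
   `[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]10`;
4. **variant classification** — compare each unique sequence with a
   known-allele catalog and label it *documented*, a *repeat pattern
   variant* (RPV) or an *intra-repeat SNP variant*, and as a *nominal
   allele variant* (the allele has a documented sequence that differs) or
   a *novel allele sequence* (no documented sequence exists for that
   allele at all).

A seeded paired-end read simulator generates ground-truth cohorts so the
whole pipeline can be validated without access to sequencing data.

## The repeat grammar and its parser

Each locus is described by a **motif template**: an ordered list of repeat
blocks (`[UNIT]` with fixed or variable copy number) and fixed-length
spacers (`N48`, `N6`) whose content is treated as opaque. A repeat region
is **decomposed** by an order-preserving parse in which every block
consumes zero or more whole copies of its unit and every spacer consumes
exactly its length.

Two permissive rules are deliberate. First, *all* copy counts — including
nominally fixed blocks — are free during matching, because observed
alleles include arrangements where a "fixed" block shrinks (e.g. a
trailing `[TCTA]3` under a `[TCTA]4` reference) and where a variable
block vanishes entirely (a DYS389I allele made only of `TCTA` repeats):
such sequences are consistent with the motif and are RPVs, not failures.
A `strict` flag restores exact reference counts for users who want it.
Second, up to *period − 1* unconsumed bases are accepted at the very end
of the region, after a terminal variable block, and become the
microvariant suffix ("13.2" = 13 repeats + 2 bases, the documented
`GA`-deletion microvariants at DYS385/DYS458). Interior partial units
fail the parse; terminal-deletion microvariants are the documented case,
so the conservative rule is used.

Ambiguity is resolved deterministically: each block is greedy
(leftmost-longest) and backtracks only as far as later blocks and spacers
require, which is equivalent to choosing the lexicographically greatest
per-block count vector. Where adjacent blocks share a unit word (the
`[AAAG]` blocks around fixed `GAAG`/`GGAG` units at DYS518), the fixed
units and the spacer pin the boundary. The test-suite cross-checks this
parser on random small templates against an independent
descending-lexicographic enumeration, and its acceptance behaviour
against a reachable-position-set dynamic program.

## Allele designation

The nominal allele of a decomposition is the **total number of repeat
units minus the reference units of blocks excluded from counting**, with
spacers never counted and any terminal tail carried as the `.k` suffix.
Most loci count every block; DYS612 excludes its leading `[CCT]5[CTT]1`
(six units), the only mask consistent with its conventional numbering
(allele 35 arises both from `…[TCT]30` and from the SNP-variant
arrangement `…[TCT]17[CCT]1[TCT]12`). The same rule expressed in bases
gives the length-based designation used at calling time:
`(region length − spacers − non-counted units·period) ÷ period`.
A deviant unit created by an intra-repeat SNP counts as a repeat — forced
by the arithmetic of observed alleles such as `[CTG]1[CTT]24` = 25.

## SNP rescue and classification

A sequence that fails its template is offered a **single-substitution
explanation**: a position where changing one base makes the parse
succeed. On success the original sequence is rewritten with the deviant
unit as its own run (`[TTTC]5[TCTC]1[TTTC]17`) and the substitution is
reported reference-base-first ("T/C SNP"). Two implementation details
matter:

* The scan is provably bounded: a rescuing position can lie at most one
  period beyond the deepest offset any partial parse of the original
  sequence consumed, because the successful parse of the rescued
  sequence is — up to the deviant unit — a valid partial parse of the
  original. The leftmost working position is reported; multi-substitution
  explanations are never attempted (no documented case requires one),
  and such sequences surface as *unclassified* for manual review.
* A sequence that parses cleanly is never offered a SNP explanation,
  even when one exists: strand slippage is the majority mechanism of STR
  variation, so the pure template parse (an RPV) wins. This is why a
  DYS635 arrangement with an extra `TGTA` is an RPV although `TGTA` is
  one substitution from `TCTA`.

Classification then reduces to catalog lookups on canonical text: an
exact (locus, decomposition) hit is *documented*; otherwise a template
match is an *RPV* and a rescued sequence a *SNP variant*; and the
(locus, allele) pair decides *nominal variant* versus *novel allele*.

## The bundled panel and catalog

The package ships a 28-locus panel (DYS19 – GATA-H4). Reference motifs
for the loci appearing in the bundled variant survey are the published
ones; motifs for the remaining loci are standard single-block motifs.
Flank anchors and spacer contents are **synthetic fixtures**: real
genomic anchor sequences are not recoverable from the survey tables, so
anchors are fixed random 16-mers, generated once and verified to occur
nowhere in any realizable panel amplicon except at their own locus
(16 nt is long enough that a chance match in a random 250-mer has
probability ≈ 6 × 10⁻⁸). One deliberate simplification: DYS448's real
repeat unit is a hexamer, outside this package's 3–5 nt unit model, so
its fixture uses a synthetic pentamer template.

The known-allele catalog is likewise a fixture whose *membership* encodes
the documented/undocumented state of the survey: every allele of the
19 nominal-variant rows has a documented entry (with a sequence that
differs from the observed one; entries invented for this purpose are
tagged `synthetic`), no allele of the 18 novel rows appears, and the
explicitly published sequences (DYS389I-9 `[TCTG]3[TCTA]6`, the DYS481-21
SNP-carrying allele, the DYS385-13.2/DYS458-17.2 microvariants) are
included under their own tags. The 19/18 split reported by the classifier
is therefore a consequence of catalog membership, not an assertion.

## The read simulator

The simulator emulates the sequencing layer that the caller consumes:
2 × 250 nt paired-end reads spanning STR amplicons.

* **Haplotypes** — one allele per locus (two distinct alleles for the
  multicopy DYS385), variable-block counts drawn uniformly from
  per-locus ranges chosen to span common allele ranges while keeping
  every amplicon within one 250 nt read.
* **Fragments** — every fragment spans the full amplicon and is padded
  to the read length with uniformly jittered random context, so both
  mates cover both anchors. A uniform-start model over the amplicon was
  considered and rejected: with 250 nt reads and 130–240 nt amplicons it
  leaves almost no read containing both anchors, which starves anchored
  calling rather than exercising it. Reads whose amplicon exceeds the
  read length trigger an explicit warning that full-span calling is
  impossible there.
* **Orientation** — each pair is swapped with probability ½, so about
  half of all reads are reverse-complemented; calling must be (and is
  tested to be) strand-invariant.
* **Errors** — substitutions only, i.i.d. per base at a configurable
  rate in [0, 0.1]; PCR stutter, quality-score realism and capture bias
  are out of scope. Base qualities are written as a constant high value
  because the caller is sequence-only.
* **Coverage** — per-locus read-pair counts; the bundled defaults span
  9–387× across loci, the range typical of capture-based enrichment,
  with the weakest markers (DYS448, DYS449, DYS518, DYS389II, DYS505)
  at the bottom. Capture dropout is not simulated by default: no
  principled rate is available, and zero-coverage loci would only
  exercise the absence of a call.
* **Determinism** — one integer seed makes the entire cohort,
  including FASTQ bytes, exactly reproducible.

What passing recovery tests on these data *do* show: the caller, floor,
compiler and classifier are mutually consistent and invert the generator
exactly at realistic coverage. What they do *not* show: robustness to
stutter artefacts, indels, quality degradation, primer-site variation or
capture dropout in real MiSeq data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_coverage` | 5 reads | floor below which an extracted sequence is not reported; the boundary (4 → dropped, 5 → kept) is tested explicitly |
| `max_mismatch` | 0 | mismatches tolerated per anchor during extraction; exact matching by default, 1 is available when anchors may carry variants |
| `read_length` | 250 nt | mate length; must reach anchor-to-anchor span |
| `error_rate` | 0 | per-base substitution probability of the simulator |
| `coverage` | 30 pairs | per-locus read pairs per allele copy (`"panel"` uses the 9–387× defaults) |
| `strict` | `FALSE` | pin nominally fixed blocks to reference counts during decomposition |

## Degenerate inputs and tie-breaks

Empty repeat regions are valid (designation 0); empty decompositions
realize the empty string. Reads matching in both orientations are
ambiguous and dropped (counted in the QC log) since their origin cannot
be resolved. Single-copy loci with several surviving sequences are all
reported and flagged rather than arbitrated. Identical (locus, sequence)
pairs with conflicting designations abort compilation — that state can
only arise from corrupted input. Among equally explanatory SNP positions
the leftmost is reported, with the base order fixed as
reference/observed.

## Scale of the bundled validation

The test-suite and the acceptance script are sized for a desk run on one
CPU: the cohort recovery check simulates 41 samples (13 AFA / 12 CAU /
16 HIS — the demonstration cohort composition) at 30× per locus with
zero error and requires the calls to equal the truth manifest exactly;
the substitution-sweep check exhaustively mutates every spacer-free
catalog sequence up to 120 nt (≈ 4,700 mutants) and cross-checks every
classification against the independent acceptor. The whole suite runs in
a few minutes.

## Known limitations

* Anchors, spacer fills and non-survey motifs are synthetic fixtures:
  results on the bundled panel validate the algorithms, not any real
  primer scheme.
* No alignment, no BAM/SAM, no quality filtering, no stutter correction,
  no indel rescue: a single substitution is the only non-slippage
  mechanism modelled.
* DYS389II physically contains DYS389I in the genome; here they are
  independent amplicons.
* Haplogroups are carried as annotations only; no prediction is
  attempted.
* Population counts are raw sample tallies; no frequency estimation is
  done.
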