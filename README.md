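# ystrseq

Sequence-based typing of Y-chromosome short tandem repeats (Y-STRs) from
raw sequencing reads, for forensic and lineage geneticists who want more
than the nominal (length-based) allele out of their data.

Capillary electrophoresis reports an STR allele as a repeat count.
Sequencing keeps the nucleotide sequence, so two alleles of the same
length can still differ — either in the arrangement of repeat units
within the locus's repeat motif (a **repeat pattern variant**, RPV) or by
a single base substitution inside a repeat unit (an **intra-repeat SNP
variant**). `ystrseq` implements the full chain from raw reads to a
classified variant table:

* **Flank-anchored allele calling** — each read (and its reverse
  complement) is searched for a locus's 5′ and 3′ anchor sequences; the
  intervening repeat region is excised, genotyped by length and retained
  as sequence. Distinct sequences supported by ≥ 5 reads become allele
  calls.
* **Nominal designation** — for a repeat region of length *L* at a locus
  with unit period *p*, fixed spacer bases *s* and non-counted reference
  units *e*: `allele = (L − s − e·p) div p`, with the remainder as the
  microvariant suffix (e.g. "13.2"). The same rule on a decomposition is
  the sum of unit-run counts minus *e*.
* **Motif decomposition** — a deterministic order-preserving parse of the
  repeat region against the locus grammar into bracketed run-length
  notation, e.g. `[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]10` (greedy
  leftmost-longest with backtracking; permissive copy counts; terminal
  partial repeats become microvariant tails).
* **Variant classification** — against a known-allele catalog: a
  template-consistent sequence is *documented* or an *RPV*; a sequence
  explainable by exactly one substitution is a *SNP variant* (reported
  reference-base-first, e.g. "T/G SNP"); and the (locus, allele) pair
  decides *nominal variant* (allele has a different documented sequence)
  vs. *novel allele* (no documented sequence at all).
* **A seeded read simulator** — 2×250 nt paired-end reads spanning STR
  amplicons at configurable per-locus coverage with an i.i.d.
  substitution error model and a ground-truth manifest, used to validate
  the pipeline end to end.

The package ships a 28-locus Y-STR panel (DYS19 … GATA-H4; synthetic
anchors), a known-allele catalog fixture, and a 37-row survey table of
observed undocumented allele sequences (19 nominal variants, 18 novel)
used as ground truth by the tests.

## Worked example

Classify an observed repeat-region sequence at DYS570, whose reference
motif is `[TTTC]n`:

```r
library(ystrseq)
panel   <- ystr_panel()
catalog <- ystr_catalog()
classify_one("DYS570", "[TTTC]5[TCTC]1[TTTC]17", panel, catalog)
#> <variant> DYS570 allele 23
#>   decomposition: [TTTC]5[TCTC]1[TTTC]17
#>   status: SNP_variant (T/C SNP at unit 5, offset 1)
#>   novelty: novel_allele
```

The 23-repeat sequence does not parse against `[TTTC]n`, but one T→C
substitution in the sixth unit explains it, so it is an intra-repeat SNP
variant — and no sequence is documented for allele 23 at this locus, so
it is a novel allele sequence. An arrangement that *is* consistent with
its motif is an RPV instead:

```r
classify_one("DYS389I", strrep("TCTA", 9), panel, catalog)
#> <variant> DYS389I allele 9
#>   decomposition: [TCTA]9
#>   status: RPV
#>   novelty: nominal_variant
```

Allele 9 is documented as `[TCTG]3[TCTA]6`; the observed all-`TCTA`
sequence is a previously unseen arrangement, but the `TCTG` block is
variable, so its absence is not an inconsistency.

End-to-end on simulated data:

```r
sim <- run_simulation("demo", coverage = 30, seed = 1)     # 41 samples
res <- run_analysis("demo/samples.tsv", out_dir = "demo/out")
head(res$report)   # unique sequences with AFA/CAU/HIS counts and types
```

The same pipeline is scriptable from a shell via
`Rscript inst/cli/ystrseq.R <simulate|analyze|classify-one> …`.

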