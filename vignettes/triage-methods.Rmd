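---
title: "Methods: tumor-only somatic triage and cohort landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-only somatic triage and cohort landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crctriage` implements a tumor-only somatic variant triage cascade for
targeted gene-panel sequencing of colorectal lesions, together with the
cohort-level landscape summaries that typically accompany such a study:
variant partitions across lesion groups, diagnostic yield, mutational
burden, gene and hotspot summaries, novelty flags, anti-EGFR resistance
markers, and gene-set over-representation. A seeded synthetic-cohort
generator with ground-truth labels makes every step testable without
patient data.

```{r setup}
library(crctriage)
```

## The filtering problem

Tumor-only panel sequencing has no matched normal, so germline variants
and sequencing artifacts must be removed by annotation rather than by
subtraction of a paired sample. The cascade runs three fixed stages per
call:

1. **Depth/quality gate.** A call fails if depth < 200× or quality
   < 100. Both comparisons are strict: a call at exactly 200×/100 passes.
2. **Functional-class gate.** Only exonic and splicing calls that are not
   synonymous proceed.
3. **Database triage.** The decision table, applied in order:
   - known somatic id (COSMIC) present and not classed benign in
     ClinVar/HGMD → retained as a *known somatic* variant;
   - known somatic id present but benign → excluded (`benign_known`);
   - no somatic id and population MAF > 1% → excluded
     (`common_polymorphism`); exactly 1% passes;
   - no somatic id and benign → excluded (`benign`);
   - no somatic id, rare or MAF-absent, not seen in the pooled normal,
     and predicted damaging → retained as a *novel candidate*;
   - otherwise excluded (`pooled_normal` when the key is in the pool,
     else `not_damaging`).

Every input call receives exactly one trace verdict, so the stage counts
always reconcile: excluded reasons plus retained equals input.

### Missing annotations

Absent ClinVar/HGMD entries are *not* benign; an absent population MAF is
treated as rare; absent prediction scores are unknown and do not count
toward the consensus. This is deliberately conservative for known somatic
variants and strict for novel candidates.

### Damaging consensus

A variant is *damaging* when at least two of the available predictors
agree (SIFT < 0.05, PolyPhen > 0.446, CADD ≥ 20) and at least two are
available. Truncating consequences — stopgain, frameshift, splice-site —
are damaging regardless of scores, since missense predictors do not apply
to them.

### Pooled normal

Controls are non-neoplastic colitis biopsies. Their calls, after the same
depth/quality gate, form a pooled set of variant keys
(`chrom:pos:ref:alt`). Only novel candidates are pool-filtered; variants
with a COSMIC id are retained even if a control carries them, because
recurrent somatic hotspots can legitimately appear in a pool of modest
size. Sample-level QC admits a sample only when mean depth exceeds 100×
and coverage fraction exceeds 0.95 (strict inequalities; unmeasured
samples are rejected).

## Cohort landscape

Variant identity throughout is the genomic key; HGVS strings are display
annotations. Distinct retained variants are partitioned by which lesion
groups carry them: `COMMON_CRC_PRECURSOR` (at least one carcinoma and at
least one precursor — IBD or polyp — carrier), `CRC_ONLY`, `CP_ONLY`,
`IBD_ONLY`, and `OTHER`. The partition follows the carrier-set
definition, not any particular example: a variant carried by both
precursor groups but no carcinoma is `OTHER`, and control-group
occupancy plays no role.

Diagnostic yield is the fraction of enrolled samples per group with at
least one retained variant, reported as a whole percent rounded half away
from zero. Burden is retained occurrences per *mutated* sample, to one
decimal. Gene summaries count cases, distinct variants, occurrences and
SNP/indel composition (typed from the HGVS coding change); hotspot tables
give per-exon and per-protein-region shares of a gene's distinct
variants. Anti-EGFR resistance flags apply a rule table (by default KRAS
exons 2–4, NRAS exons 2–4, BRAF exon 15, PIK3CA exon 20) over carcinoma
samples only.

```{r example}
calls <- load_catalog_calls("common")
sheet <- catalog_sample_sheet()
res <- run_cascade(calls)
part <- partition_by_group_occupancy(res$retained, sheet)
table(part$partition)
head(gene_summaries(res$retained, sheet), 3)
```

## Bundled catalogs

Three recurrent-mutation catalogs ship as checksummed plain-TSV fixtures:
mutations shared between carcinomas and precursor lesions (16 rows with
per-group occurrence counts), database-known variants not previously
associated with colorectal carcinoma (29 rows in 21 genes), and
database-absent novel variants (10 rows: 6 PIK3CA, 4 FBXW7).
`load_catalog_calls()` expands printed occurrence counts into per-sample
annotated calls whose alleles are derived from the HGVS string
(placeholder `N`-anchored alleles for indels, since no reference sequence
is shipped — identity stays consistent because every consumer derives
alleles the same way).

## Synthetic cohorts

`generate_cohort()` draws a seeded cohort under configurable study
conditions: group sizes (controls 20, IBD 20, polyps 38, carcinomas 62),
per-group probability that a sample carries somatic mutations, and a
zero-truncated Poisson somatic burden whose rate is solved so the
truncated mean matches the configured mean. Somatic variants are drawn
from a finite catalog so recurrence arises naturally; labels distinguish
`somatic_known`, `somatic_novel`, `germline_common`, `germline_shared`
(planted in controls and lesions alike, so pooled-normal subtraction can
be exercised) and `artifact` (depth or quality forced under the gate).
The gene panel is a 96-gene mock interval table — an explicit stand-in,
weighted so TP53 and APC accumulate the most variants.

Every generated call carries a ground-truth label, so cascade
sensitivity and specificity are measured against the generator's label
table rather than against re-derivations of the cascade itself.

## Over-representation analysis

`hypergeometric_ora()` computes the upper-tail hypergeometric probability
P(X ≥ k) for k mutated genes inside a set of size K, n mutated genes in a
background of N (the gene panel), with Benjamini–Hochberg adjustment
across sets. Gene sets are intersected with the background before
testing; k = 0 yields p = 1 under the upper-tail convention. The test
suite verifies the implementation against exact combinatorial enumeration
for every background size up to 30.

## Verification

The package's test suite covers, among other things:

- exhaustive truth-table equivalence of the database-triage decision
  against an independently written rule oracle (756 combinations);
- order-invariance of the cascade and monotonicity under stricter
  thresholds;
- 100% exclusion of planted artifacts and common polymorphisms and 100%
  retention of planted known somatic variants on seeded cohorts;
- recovery of generator burden means and SNP fraction within three
  standard errors;
- HGVS round-trips and printed-type agreement on all 55 catalog rows.

`scripts/acceptance.R --seed <int> --out <path>` reruns the headline
computation against the installed package and writes the quantities as
JSON.

## Limitations

The cascade consumes annotated calls; alignment, variant calling, and
annotation itself are out of scope. Tumor purity and per-variant allele
fractions are not modeled. The merge of two callers' outputs assumes
their quality scores are on comparable scales. The shipped panel
intervals, protein regions and pathway sets are compact stand-ins meant
for testing and demonstration, not clinical use.
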