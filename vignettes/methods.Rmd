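---
title: "Models and design choices in vtburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in vtburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtburden)
```

This vignette is the package's account of the statistics it implements, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The variable-threshold burden test

Gene-based collapsing tests compare the number of cases and controls that
carry at least one qualifying rare variant in a gene. "Qualifying" depends
on a deleteriousness cutoff for missense variants, and the best cutoff is
gene specific: a gene acting through complete loss of function wants a
permissive set including all LGD variants, while a gain-of-function gene
may be driven by a narrow band of high-scoring missense changes. The
variable-threshold test therefore searches the gene's own observed REVEL
scores for the cutoff *t* maximizing an inner enrichment statistic, and
pays for that search by repeating it inside every label permutation.

Choices made here:

* **Inner statistic.** The one-sided hypergeometric tail of the 2×2 carrier
  table, on a −log₁₀ scale. It is exact at the small counts typical of rare
  variants and is a monotone function of the carrier split under fixed
  margins, which makes the permutation distribution cheap to sample (only
  the case labels of carriers matter, and their count is hypergeometric).
  A binomial tail is available (`statistic = "binomial"`) for comparison
  with scans that describe their per-gene test that way.
* **Candidate thresholds.** The unique REVEL values among the gene's
  missense variants, descending; for the LGD-plus-D-Mis configuration an
  additional LGD-only candidate (threshold +∞) is included. Tied scores
  share one threshold.
* **Permutation p-value.** `(1 + #exceedances)/(B + 1)`, with exceedances
  counted at ≥ the observed maximum. The loop stops early once 50
  exceedances accumulate — by then the estimate is far above any reporting
  threshold — so the attainable minimum is 1/(B+1). `early_stop = Inf`
  disables this for oracle comparisons. Default B is 10,000; the scans in
  the test suite use B between 400 and 5000 to keep runtimes in minutes.
* **Discreteness.** With few carriers the permutation distribution of the
  maximized statistic has ties, and counting ties as exceedances makes the
  p-value conservative (the measured median null p-value is slightly above
  0.5). This is a property of any honest discrete permutation test: null
  p-values are *not* exactly uniform, so calibration is asserted as a
  type-I error rate within its binomial band and a genomic-control lambda
  near 1, not as distributional uniformity.

Two configurations are tested per gene — LGD + D-Mis for loss-of-function
genes, D-Mis alone for gain-of-function or dominant-negative genes — and
multiplicity is handled jointly over all 2 × G p-values: Benjamini-Hochberg
q-values with a q < 0.1 reporting flag, and a Bonferroni threshold of
α / n_tests (0.05/40,000 = 1.25 × 10⁻⁶ at genome scale, the round number
being the conservative version of 2 × 18,939 genes with rare variants).

## Filters

The cohort inclusion rules use the comparators as printed in the field's
pipelines: allele frequencies are strict `<` (cohort < 5 × 10⁻⁴, population
< 1 × 10⁻⁴, both stored as fractions — never percentages), coverage is
strict `>` 0.9, allele balance and caller consensus are `≥`. The
rare-variant *definition* elsewhere uses `≤ 1 × 10⁻⁴`; both constants live
in `default_thresholds()`. The "90% of the target region at depth ≥ 10"
criterion is ambiguous between a per-sample and a per-site reading; it is
implemented as a per-variant fraction-of-samples-with-DP≥10 field with
threshold 0.9. Rejections are attributed to the first failing rule in the
documented order, so the audit counts always sum to input − kept.

The de novo cascade applies the SNV/indel-specific VQSR tranche bounds
(99.7 / 99.0), Fisher strand ≤ 25, quality-by-depth ≥ 2, proband rules
(≥ 5 alt reads, alt fraction ≥ 20%, GQ ≥ 60, population AF ≤ 0.01%), and
both-parent rules (≥ 10 ref reads, alt fraction strictly < 5%, GQ ≥ 30),
returning every failed rule per record.

## De novo background model

For each gene the coding sequence (with one flanking base each side) is
scanned; each possible substitution contributes its trinucleotide-context
rate μ(5′, ref, 3′ → alt) to the consequence class obtained by translating
the mutated codon. Class rates therefore sum exactly to the gene's total
substitution rate, and are invariant to how exons split the sequence. Two
derived classes are not pure substitution classes and need modelling
constants the source pipelines do not print:

* `lgd_rate = non_rate × lgd_factor` (default 2): frameshift indels and
  splice-site variants are taken as roughly one extra nonsense-equivalent
  rate unit, a common order of magnitude for coding indel models.
* `dmis_rate = mis_rate × dmis_fraction` (default 0.2): the share of
  missense changes expected to exceed a REVEL ≈ 0.5 deleteriousness cutoff;
  0.2 is consistent with published expected-count tables in which the
  D-Mis expectation is about a fifth of the missense expectation.

The shipped `demo_rate_table()` is a synthetic demonstration table — uniform
with a 10× CpG-transition boost, the dominant feature of empirical context
tables; real studies supply their table as a 192-row TSV
(`read_rate_table()`). Gene-level `mappable_fraction` multiplies all rates.

Expected counts are m₀ = 2 · n_trios · Σ_genes rate (two transmitted haploid
genomes per trio), optionally restricted to a gene set such as genes highly
expressed in developing lung/heart. The exact Poisson test uses the
total-probability two-sided convention — the sum of Poisson(k; m₀) over all
k whose probability does not exceed that of the observed count — which
reproduces published two-sided p-values that a plain doubled tail does not
(for 29 observed vs 11.85 expected the one-sided tail alone is ≈ 1.8 × 10⁻⁵,
the two-sided total-probability value ≈ 2.5 × 10⁻⁵). Estimated risk
variants are round(m₁ − m₀), half away from zero, floored at 0 (reproducing
17, 15, 12 and 10 from the published pairs), and the attributable fraction
divides by n_trios. When known risk genes are excluded from the observed
count, the expectation is by default left unchanged (the published
22-variant computation against the unmodified 11.85 expectation implies the
same choice); `exclude_from_expected = TRUE` removes them from both sides.

## Expression ranking

Relative expression is the fraction of cells of a type with a nonzero
count; cell types with fewer than 70 cells are dropped as unstable. Cell
type columns are z-scored before PCA (`scaling = "none"` is available since
upstream scripts do not always state their scaling), loadings are fit on
all genes, and every gene gets a score on the chosen component — the second
component, in datasets of this shape, typically captures the coordinated
endothelial signature that separates vascular-disease risk genes from the
bulk. The component's sign is arbitrary, so it is oriented to make the
known set's mean score positive. Top-quantile enrichment of a candidate set
uses expected = |set| × q and a one-sided binomial tail; with 7 of 12 genes
in the top 5% this definition gives enrichment 7/0.6 ≈ 11.7 — published
figures computed with an unstated denominator are not asserted.

## The synthetic-data generator

The generator emulates the structure the statistics rely on, at a scale
that keeps full runs in seconds to minutes:

* **Cohorts.** Default 500 cases / 5000 controls (a 1:10 ratio like the
  large consortium studies, at roughly a third scale in cases), baseline
  carrier frequency 0.002 per gene for qualifying rare variants, one
  European-like stratum. Risk genes multiply the control carrier frequency
  by `fold` in cases; their case variants are drawn from the
  high-deleteriousness Beta(12, 2) component with probability
  `score_shift`, against a null mixture 0.7·Beta(2, 6) + 0.3·Beta(6, 3) —
  a bimodal score distribution under which a gene-specific optimal
  threshold exists. Carriers are collapsed (at most one qualifying variant
  per gene per sample) and cohort allele frequencies are recomputed from
  realized carrier counts, so frequency bookkeeping is exact by
  construction. QC fields are drawn in the passing range; filter behavior
  is tested with explicitly corrupted fixtures instead.
* **Trios.** Per-class counts are Poisson with the model's own expectation;
  variants land on genes proportionally to their class rates. An
  `artifact_fraction` of evidence records is corrupted to violate exactly
  one randomly chosen de novo filter — these exercise the cascade and are
  excluded from the true-variant list.
* **Expression.** A per-gene Beta(2, 10) propensity times a per-type
  factor, observed as binomial fractions over `cells_per_type` cells;
  enriched genes are multiplied by the enrichment factor in the designated
  types (capped at 0.98). Defaults (14 cell types, 200 cells each, a
  12-gene enriched set among ~1000 genes, 3 enriched types) mirror the
  shape of curated single-cell compendium summaries.
* **Seeding.** One root seed; each generator derives a child seed at a
  fixed offset, so outputs are bitwise reproducible and adding a generator
  never shifts another's stream.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium and haplotype
structure, ancestry stratification and batch effects between sequencing
sources (real studies mix platforms and rely on synonymous-rate
calibration, implemented here as `synonymous_calibration()`), indel
context models, and heterogeneous per-sample coverage.

## Problem sizes and numerical choices

The calibration experiments in the test suite use: 1000 null genes at
500/5000 samples with B = 400 for the type-I and lambda checks (carrier
frequency 0.005, chosen so the permutation statistic has resolution below
p = 0.05); B = 20,000 against the exhaustive 252-permutation oracle on a
10-sample instance; 1000 replicate trio cohorts at a 2× enrichment over an
expectation of ≈ 11 for recovery of the enrichment estimate; and a
1012-gene expression universe for the top-5% recovery check. Power
calculations enumerate the binomial distributions of both carrier counts
exactly and integrate the pooled-variance z-test rejection region, because
at carrier counts of order 10–20 the closed-form normal approximation
misses the true rejection rate by a few percentage points (the closed form
remains available as `method = "normal"`).

Degenerate inputs are defined rather than accidental: a gene with no
qualifying variants reports p = 1 with an undefined cutoff; an empty scan
reports zero tests; lambda requires at least 10 p-values and rejects the
all-ones vector; `exact_poisson_test` requires m₀ > 0; a constant
expression matrix is an error.

## Known limitations

* Only set-level de novo burden is implemented, not per-gene de novo
  significance or multi-hit discovery statistics.
* The de novo indel rate is a scalar multiple of the nonsense rate, not a
  sequence-context model.
* Covariate-adjusted association (ancestry PCs, mixed models, SKAT-style
  tests) is out of scope; the permutation null assumes exchangeable labels
  within one stratum.
* Permutation p-values are discrete; at small B, q-values and lambda
  inherit that granularity.
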