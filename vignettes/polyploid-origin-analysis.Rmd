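---
title: "Inferring the origin of spontaneous polyploids from ploidy and private microsatellite alleles"
author: "ploidyOrigin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the origin of spontaneous polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyOrigin)
```

## The inference problem

A functional tetraploid (4n) sturgeon dam crossed with a functional
hexaploid (6n) sire should yield pentaploid (5n) offspring: a reduced
2n oocyte fused with a reduced 3n spermatozoon. Offspring whose DNA
content indicates a higher ploidy carry an extra chromosome set whose
origin is the question. Three mechanism families can supply it, and
each leaves a distinct, testable signature:

| mechanism | zygote | genotype signature |
|---|---|---|
| normal meiosis | 5n | baseline |
| PB2 retention (second-division restitution) | 7n | more dam alleles than a reduced oocyte, but *not* the dam's full genotype |
| apomixis / premeiotic endomitosis (clonal oocyte) | 7n | the dam's complete multilocus genotype |
| dispermy | 8n | excess equals the *sire's* gamete ploidy |

The package's chain is: call functional ploidy from DNA content; group
anomalous offspring against euploid full siblings; count parent-private
alleles per locus; test for a directional increase; and walk an
explicit exclusion sequence to a verdict with an evidence trail.

## Observation model: presence-only genotypes

Polyploid microsatellite electropherograms do not yield reliable allele
dosage, so a genotype here is the *set* of distinct fragment lengths at
a locus (`GenotypeTable`, set semantics enforced on read). All
downstream statistics are built on presence only: a private allele
observed in an offspring scores 1 regardless of how many copies it may
have. Missing genotypes are absent rows, contribute zero counts, and
are reported by `validateCrossTable()` rather than treated as errors,
since no principled imputation exists for presence-only data.

## The private-allele battery

An allele is dam-private if present in the dam's set and not the
sire's (`classifyAllele()`; shared alleles are uninformative by
construction, non-parental alleles — artifacts or mutations — are
excluded and logged). Loci where the parents share every allele cannot
produce private alleles and are dropped before testing, which reduces
the degrees of freedom accordingly.

With L informative loci and two equal-sized offspring groups, the
per-locus group sums form L paired observations. `pairedT()` computes
t = mean(d) / (sd(d)/sqrt(L)) with df = L − 1 and a two-sided p from
the t distribution. Design choices:

* **Sidedness.** p is reported two-sided; the directional hypotheses
  (H1: dam-private increase, H2: sire-private increase, H3: both) each
  additionally require mean(d) > 0. This keeps the reported p
  conventional while preventing a significant *decrease* from
  supporting an increase hypothesis.
* **Degenerate differences.** All-zero differences give exactly t = 0,
  p = 1 (the expected outcome for sire-private counts under a maternal
  duplication). Zero variance with non-zero mean is reported as an
  infinite t with p = 0 and flagged, rather than silently dividing by
  zero.
* **Normality.** Shapiro–Wilk on the differences
  (`shapiroWilkCheck()`) is advisory: the battery warns and proceeds,
  since L is small and the paired t is the field's convention for this
  design.
* **Equal group sizes.** The fold change of group totals (e.g. 63/35 =
  1.8) is only interpretable with equal group sizes; unequal groups
  trigger a warning, and `classifyCross()` size-matches the euploid
  reference group deterministically (first siblings in table order).

## Ploidy calling

`callPloidy()` uses a nearest-candidate rule on |measurement −
candidate × per-set reference| with a relative no-call tolerance
(default 0.15, roughly half the relative gap between adjacent
candidates at 5n–7n) and ties broken toward the lower ploidy with a
warning. The rule is scale-invariant, so absolute pg and
ratio-to-standard measurements are handled identically.

The per-set reference is deliberately a *configuration input*, not
jointly estimated: the two cohort means this design produces (8.98 pg
at 5n, 15.02 pg at 7n) imply different per-set contents (1.796 vs
2.146 pg/set), a calibration gap the package exposes rather than
resolves — per-group references and the no-call band are the honest
interface. Feulgen densitometry readings convert to pg through
`estimateGenomeSize()`, linear in IOD through standards of known
content (defaults: diploid and triploid tench, 2.02 and 3.10 pg).

Chromosome-number predictions (`predictChromosomeNumber()`) apply the
same gamete arithmetic to parental counts with halves rounded half-up,
since sturgeon counts are approximate (microchromosomes): 245 + 184 =
429 for an unreduced-oocyte heptaploid, against a modal observed
430 ± 10.

## Mechanism classification

`inferMechanism()` walks the exclusion sequence: excess 0 → normal;
excess = sire gamete ploidy → polyspermy (and conversely, polyspermy is
arithmetically excluded whenever the sire's gamete ploidy cannot
produce the excess); excess = dam gamete ploidy → maternal duplication,
split by clonal identity (clone) versus non-identity plus a supported
H1 (PB2 retention); anything else, or conflicting evidence, is
UNRESOLVED. When both parents have equal gamete ploidies the excess is
uninformative about the parent and the verdict falls to H1 vs H2 alone
rather than guessing.

The clonal-identity test (`maternalIdentityFraction()`) asks, per
locus, whether the offspring's alleles (minus sire-only alleles)
contain the dam's full set. The default threshold is 1.0 — the
exclusion of clonal mechanisms rests on *any* non-identity. Under
allele dropout a true clone can fail single loci, so
`dropoutIdentityThreshold()` derives a tolerant threshold from the
dropout model itself: tolerate the expected number of dropout-broken
loci (for 8 loci, dropout 0.02, ~4 dam alleles per locus this is one
locus, threshold 7/8). At dropout 0 the rule reduces to the strict
default.

The allele-data cannot formally separate PB2 (meiosis II) from
first-polar-body retention; the verdict label follows the convention of
naming the meiosis-II event, and the evidence trail records the
recombination-bearing maternal duplication that is actually observed.

## The simulator

`simulateCross()` / `simulateMixedCross()` generate the cross with full
ground truth (every allele copy tagged by homolog and parent of
origin), so recovery experiments have an exact standard.

* **Inheritance.** Gametes take a uniformly random half of the homolog
  set, independently per locus: random bivalent pairing, no
  preferential pairing, no double reduction — the null model of
  polysomic inheritance, chosen because nothing in this design
  identifies a pairing structure.
* **PB2 retention.** Modeled at the allele level: a reduced set is
  duplicated, and each duplicate independently, with probability `r`,
  takes the allele of a uniformly chosen non-selected homolog
  (heterozygosity restored by a centromere–locus crossover); with
  probability 1 − r the sister copy is kept. The single parameter `r`
  subsumes map distance and crossover bookkeeping, because the
  observable is private-allele presence only. The group-level fold
  change of dam-private alleles is monotone in `r`, spanning ≈1 (r = 0,
  indistinguishable from a reduced oocyte) to its maximum below 2 at
  r = 1; `calibrateR()` inverts an observed fold change to `r` on a
  grid. The default r = 0.8 is the effective value consistent with the
  ~1.8-fold increase this design is built around.
* **Clonal arm.** Apomixis and premeiotic endomitosis are one arm
  (`APOMIXIS_CLONE`) since both produce oocytes genetically identical
  to the dam — the same criterion that excludes them. Polyspermy is
  modeled as dispermy (two independent reduced sperm). First-polar-body
  retention is out of scope.
* **Defaults.** 4n dam × 6n sire, 8 unlinked loci, allele pools of 12
  lengths per locus in 4 bp steps (a polymorphic tetranucleotide
  microsatellite panel; pool size sets parental heterozygosity and the
  supply of private alleles), 7 offspring per cohort (the analyzed
  group size of the design), observation dropout 0 by default and 0.02
  in the dropout-tolerant experiments. All randomness flows from one
  generator seeded per call; sub-operations never reseed.
* **Cytometry.** Per-nucleus DNA content is Gaussian around
  ploidy × per-set pg with CV 0.02; a specimen's measurement is the
  mean of 3000 nuclei, matching cytometric practice.

## What the simulations do and do not show

The validation experiments (in `tests/testthat/`) use these sizes,
chosen to estimate each quantity to useful precision while keeping the
suite quick: type-I error of the dam-allele test from 1000 replicate
euploid sibling pairs (7 + 7, 8 loci) — the two-sided rejection rate
sits within 3 standard errors of the nominal 0.05; power under PB2
retention (r = 0.8, dropout 0.02) from 100 replicates; cross-level
mechanism recovery over 200 mixed-mechanism crosses (50 per arm);
single-locus PB2 gamete distributions against brute-force enumeration
(10,000 draws, chi-square); and calibration recovery of a planted
r = 0.6 at 500 offspring per arm.

Passing these shows the chain is correct *under the generator's
assumptions*: unlinked loci, uniform polysomic segregation, independent
per-allele dropout, Gaussian cytometry noise. Real data add features
the generator deliberately omits — stutter and binning artifacts,
locus-specific amplification failure, preferential pairing, double
reduction, null alleles — so simulated power and accuracy are upper
bounds, not guarantees, for field data. The degrees of freedom of the
battery, however, are small (loci, not individuals), so its behavior
transfers well wherever the per-locus counts themselves are sound.

## Known limitations

* Dosage-free genotypes discard information; with reliable dosage the
  maternal-contribution test would gain power.
* The identity test is conservative under heavy dropout; below ~6
  informative loci the clone/PB2 distinction becomes fragile.
* `r` is an effective, locus-averaged parameter; per-locus map
  distances are not modeled.
* The per-set DNA-content reference must come from the user's own
  standards; the package surfaces, but cannot reconcile, references
  that disagree between cohorts.
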