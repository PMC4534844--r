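---
title: "Methods: permutation-based DMR calling for stress time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based DMR calling for stress time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psimeth)
```

## The problem

Whole-genome bisulfite sequencing reads out 5-methylcytosine at single-base
resolution: at each cytosine reference position, a basecall of C indicates a
methylated (bisulfite-protected) cytosine and a T an unmethylated one.  In
plants, methylation occurs in three sequence contexts (CG, CHG and CHH with
H ∈ {A, C, T}); CHH methylation is asymmetric and must be re-established
after every replication, which makes it the most dynamic readout of
stress-induced epigenome remodelling.  `psimeth` implements a complete
desk-scale pipeline for this kind of study: per-cytosine differential
methylation testing between condition groups (e.g. nutrient-starved vs
control roots), assembly of significant cytosines into differentially
methylated regions (DMRs), annotation of DMRs against gene and
transposable-element (TE) features, and classification of whether a DMR's
methylation change persists after the stress is removed.

## Methylation levels and non-conversion correction

The *weighted methylation level* of a scope (a region, a context, a whole
sample) is

$$ \hat m = \frac{\sum_i mc_i}{\sum_i t_i}, $$

the fraction of all basecalls at cytosine positions that were cytosine —
not a mean of per-site fractions, so deeply covered sites carry
proportionally more weight (`weighted_level()`).  Bisulfite conversion is
imperfect: a fraction ε of unmethylated cytosines escapes conversion and
reads as methylated.  ε is estimated from an unmethylated spike-in
chromosome (lambda phage DNA added at 0.5% w/w before conversion) as the
methylated basecall fraction there (`estimate_nonconversion()`); typical
values are ~0.5% and the estimator warns above 5%.  Levels are corrected by
literal subtraction clamped at zero, `max(0, m − ε)` (`correct_level()`).
The multiplicative inversion `(m − ε)/(1 − ε)`, which exactly inverts the
read-level contamination model `observed = p + (1 − p)ε`, is available via
`method = "rescale"`; subtraction is the default because the observable
bias difference, `p·ε`, is below 0.5% of the level everywhere.  Correction
is applied per sample (each library has its own conversion efficiency)
before any group comparison; samples with zero coverage in a region are
reported missing, never imputed.

## The per-cytosine test

At each cytosine (pooled CNN scope), covered samples form an r × 2
contingency table of (methylated, unmethylated) read counts.  With observed
cell frequencies $f_{ij} = n_{ij}/n$ and independence expectations
$e_{ij} = r_i c_j / n^2$ (products of row and column marginals), the test
statistic is the root-mean-square deviation

$$ T = \sqrt{\tfrac{1}{rc} \sum_{ij} (f_{ij} - e_{ij})^2 }, $$

which is zero exactly at independence and, unlike Pearson's X², remains
well-behaved for the very sparse tables typical of ~20× coverage.  Its null
distribution is simulated by drawing, for each permutation, all n reads
multinomially over the cells with probabilities $e_{ij}/n$; each permuted
table is scored by the same statistic with its own marginals.  Sampling
stops early once 100 permutations have reached the observed statistic
(their p-value is then already known to be large) or at the permutation cap
(10,000 by default).  The p-value uses the add-one estimator
$(x + 1)/(B + 1)$, which is never zero — a permutation p of exactly 0 is
invalid and would break the step-up FDR calculation downstream.

Two open design points are resolved as follows and both alternatives are
kept available:

* **Rows are samples**, not positions: a per-cytosine independence test is
  only defined with samples as rows, and this uses the replicate structure.
  `pool_replicates = TRUE` collapses the table to a 2 × 2 condition table.
* The comparison `permuted ≥ observed` uses a 10⁻¹² tolerance so that exact
  ties (frequent in tiny discrete tables) count as exceedances; this is
  what makes the estimator match exhaustive enumeration on small tables.

Per-site seeds are derived deterministically from the master seed and the
site's coordinates, so results are independent of the order in which sites
are tested (and hence of any parallel execution plan).

## FDR calibration, DMR assembly and consistency filtering

The significance threshold is the **largest p-value cutoff that still
satisfies the FDR target**.  The default calibration is the
Benjamini–Hochberg step-up rule (largest sorted $p_{(k)} \le kq/m$,
`select_fdr_cutoff(method = "bh")`); an empirical-null variant (estimated
FDR from p-values recomputed under random group relabelings) is provided
for designs where the relabeled null is informative — note that for
sample-rows tables the statistic does not depend on the group labels at
all, so the relabeled null is only meaningful under 2 × 2 pooling.

Significant cytosines are merged greedily left-to-right into blocks when
they lie on the same chromosome, share the same direction of change
(hyper/hypo from pooled group levels), and are within 200 bases of the
previous member (`merge_sites()`).  Block boundaries are the first and last
member positions, unpadded, which reproduces region-size statistics on the
order of 200 bp from site geometry alone.  Blocks with fewer than 8
significant sites (5 in the Arabidopsis-style profile) are discarded.

The replicate-consistency rule ("at least k of n stressed replicates
differentially methylated, allowing n − k swapped samples") is not fully
specified by its verbal form, because "a differentially methylated sample"
is undefined.  We operationalize it with a parameter-free midpoint
criterion (`consistency_filter()`): with m the midpoint of the two group
means of the region's corrected CNN level, a sample is consistent iff its
level lies strictly on its own group's side of m in the region's direction;
the region passes iff each group has ≥ k consistent samples.  This is
monotone in effect size, symmetric in the groups, and reduces to the stated
tolerance (7-of-9 permits 2 swapped samples per group).  An optional margin
around the midpoint (default 0) is available for stricter separation.

Configuration profiles bundle the study-design thresholds: `rice_root`
(FDR 0.01, ≥8 sites, 7-of-9), `rice_shoot`/`panicle` (FDR 0.05, 3-of-3),
`arabidopsis` (FDR 0.2, ≥5 sites, 2-of-3).  Multi-timepoint pooling (three
late timepoints × three replicates into one 9-replicate group) is expressed
purely through the sample sheet's group assignment; there is no
special-case code.

## Annotation

Each DMR is assigned to its nearest gene with a signed, strand-aware
distance: 0 inside the gene span (largest overlap wins, ties to the
lexicographically smaller id), negative upstream of the TSS, positive
downstream of the TES, and binned as gene body, 0–1 kb, 1–2 kb, 2–4 kb,
4–6 kb, >6 kb.  The genome-normalized bin distribution divides the DMR
count per bin by the number of genomic regions in that bin category; since
"regions in a bin category" has no canonical definition, we operationalize
it by tiling the genome into fixed 200-bp windows (about one mean DMR) and
classifying each tile's midpoint with the same nearest-gene rule.  The tile
size is an exposed parameter and results should be reported with it.
TE overlap requires ≥1 bp in 1-based inclusive coordinates; a DMR may carry
several TE classes.  Expression classes for nearest genes
(`up>4`, `up2-4`, `down>2`, `ns`, `absent`) gate on the DE table's FDR
(q < 0.05) before binning the fold change at 2× and 4×.

## Persistence and temporal ordering

Region-level group tests are Welch two-sample t-tests on per-sample
corrected CNN levels (the pooled-variance variant is a flag; the unequal
variance default is the safer choice when stress alters both mean and
variance of methylation).  P-values are BH-adjusted within each comparison
family.  A region is **persistent** when control-vs-stress and
recovery-vs-control are both significant but stress-vs-recovery is not
(the recovered tissue retains the stressed state); **transient** when the
stress effect is significant but recovery has returned to control;
anything else is ambiguous.  Declaring "not significant" accepts a null —
intrinsically weak evidence at n = 3 — so the three q-values are always
reported next to the call, and with triplicates the classifier has an
irreducible error rate of roughly the α-level per branch.  The
panicle-style profile relaxes α to 0.1.  `onset_summary()` applies the same
machinery per timepoint to order transcriptional vs methylation onset, and
`cluster_samples()` performs Euclidean/average-linkage agglomerative
clustering of samples in DMR-level space (Newick export via ape).

## The synthetic-data generator

`simulate_experiment()` produces a complete miniature study: a
two-chromosome 120-kb genome plus a 4-kb unmethylated spike-in chromosome,
16 genes, 30 TEs with a MITE-heavy class mix (69% MITE), cytosines every
~30 bp with a CHH-dominant context mix, plant-like baselines (TEs: CG 0.80,
CHG 0.50, CHH 0.05; background: CG 0.10, CHG/CHH 0.02), coverage ~
Poisson(20), and 0.5% read-level non-conversion.  Implants are 12-site CHH
hypermethylation runs (Δ = 0.5 by default) placed inside disjoint TEs near
genes, mirroring the TE-proximal hypermethylation such stress studies
report; a matched expression table marks each hyper implant's nearest gene
as strongly induced.  The default design is 9 control vs 9 stressed samples
(three replicates at each of three late timepoints); `design_recovery()`
adds a resupply group for persistence studies, with implants split between
persistent and transient classes.

Replicate noise is beta-binomial with intra-class correlation ρ = 0.01
rather than pure binomial, so the consistency filter has realistic
between-replicate variation to work against; ρ = 0 recovers the binomial
exactly.  Non-conversion is injected at the read level
(`observed = p + (1 − p)ε`), which makes the generator double as the oracle
for the correction step.  What the generator does **not** emulate: sequence
composition, read-level error profiles, mapping bias, coverage
autocorrelation along the genome, and long-range methylation structure —
passing tests demonstrate the statistical machinery on the stated count
model, not robustness to alignment artefacts.

## Calibration properties and a known limitation

The test suite verifies, among other things: exact agreement of the RMS
statistic with hand-derived values; convergence of Monte-Carlo p-values to
exhaustive multinomial enumeration on all 2 × 2 tables with ≤ 8 reads;
super-uniformity of permutation p-values under a multinomial null;
recovery of ≥ 90% of implanted DMRs at Δ = 0.3, 20× coverage, 9v9 with zero
DMRs on null genomes in ≥ 95% of seeds; and ≥ 90% correct
persistent/transient calls at n = 3.  Problem sizes (2,000-site mixtures,
20 seeds, 120-kb genomes) are chosen so the full suite runs on a laptop in
minutes.

One limitation deserves emphasis.  The multinomial permutation null models
reads as exchangeable across samples given the marginals.  Replicate
overdispersion — any real biological between-replicate variation —
violates that null at *every* site, truly differential or not, and inflates
the site-level false-discovery proportion beyond the nominal target even
though the same code is well calibrated at ρ = 0 (the suite demonstrates
both).  `scripts/acceptance.R` reports the empirically measured FDP of the
full procedure under the generator's default ρ = 0.01 exactly as computed.
The relabeling-based empirical-null calibration cannot repair this for
sample-rows tables (the statistic is label-free), and under 2 × 2 pooling
it collapses power whenever the truly-differential fraction is large.
Users who need strict site-level FDR under replicate heterogeneity should
treat the region-level filters (minimum site count and k-of-n consistency),
which this pipeline applies downstream, as the operative error control —
on null genomes the assembled-DMR false-positive rate is essentially zero —
or use a dispersion-aware model outside this package's scope.
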