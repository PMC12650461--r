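---
title: "Methods: simulation-verified downstream analysis of strain-contrasted T-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-verified downstream analysis of strain-contrasted T-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mregnet)
```

## Scope and design

`mregnet` re-implements, as transparent and individually testable stages, the
downstream analysis of a bulk RNA-seq contrast between antigen-specific
CD4^+^ and CD8^+^ T cells from a myocarditis-resistant and a susceptible
mouse strain: FPKM quantification and ordination, negative-binomial Wald
differential expression, over-representation and ranked-list enrichment, a
TF--target prior network stage that ranks master regulators by DEG
connectivity, and 2^−ΔΔCt^ qPCR validation. The pipeline starts at the
gene-level count matrix; read QC, alignment and counting are upstream of its
scope.

Because no raw sequencing data accompany the study design this package
models, every stage is instead verified against a seeded synthetic-data
generator that plants known truths — DE genes of known log2 fold change,
coherently shifted gene sets, and master transcription factors whose target
lists are loaded with planted DEGs — so that recovery, calibration and
closed-form behaviour can be asserted by the test suite and the acceptance
script. The package therefore makes no claim to reproduce any particular
study's gene lists or enrichment tables; it reproduces the *procedures* and
demonstrates they recover planted truth under the stated study conditions.

## The synthetic study and what it does (not) emulate

`sim_config()` defaults encode the assumed design: 2 strains
(`resistant`, `susceptible`) × 2 cell types (`CD4`, `CD8`) × 3 biological
replicates; 2,000 genes; NB counts with a single shared dispersion
α = 0.1 (Var = μ + αμ²); per-gene baseline log2 abundance uniform on
[1, 9]; library sizes uniform on [0.8, 1.2] million; gene lengths uniform
on [500, 5000] bp, drawn once and independent of expression.

Planted effects are additive on the log2 scale. 5% of genes are DE between
strains within each cell type at |log2FC| = 2.5 with random sign; half of
each cell type's panel is shared with the other (same genes, same signs),
emulating strain differences common to both T-cell subsets — this shared
component is what makes the strain contrast the leading principal
component, with subset-specific DE and a milder cell-type effect (10% of
genes at |log2FC| = 1) forming the second axis. Relative abundances are
renormalised within each sample, so planted ratios are subject to the mild
compositional distortion real sequencing has; the planted-effect fidelity
test budgets for this (mean recovered log2FC within ±0.5 at 10
replicates).

Gene sets: 50 sets of 15--50 genes; 4 "shifted" sets are ≥ 90% composed of
same-direction planted DE genes (directions alternating), the remainder
drawn uniformly from non-DE genes. When a drawn size would demand more
same-direction planted genes than exist, the set is shrunk rather than the
composition diluted, keeping the ≥ 80% contract under any seed. The prior
network assigns 50 TFs (themselves genes) 10--30 targets each across three
source-tagged edge lists with ~20% of assertions duplicated into a second
source; one master TF receives 10 planted-DEG targets while non-masters are
capped at 4, so the 2× loading rule holds with margin. The qPCR table
follows Ct = base − (planted log2FC if first strain) + N(0, 0.2 cycles),
with a flat reference gene at Ct 18 and duplicate wells.

Not emulated: batch effects, gene-specific dispersion trends, outlier
counts, length--expression correlation, UMI structure, or read-level
artifacts. Passing tests therefore demonstrate correctness of the
procedures under idealised NB data, not robustness to real-data pathology.

## Quantification

FPKM(g, s) = count / ((length/10³) · (total/10⁶)), with each sample's total
assigned counts standing in for "million mapped reads" (true mapped totals
are unavailable once the pipeline starts at the matrix). A gene counts as
*expressed* in a strain × cell-type group when its raw counts summed over
the group's replicates reach 10: at n = 3 a per-replicate rule is unstable,
and the group sum is the least arbitrary reading of a bare "cutoff of 10".
Both the threshold and the grouping are arguments. PCA runs on
log2(FPKM + 1) over all genes (no variable-gene preselection), samples as
observations, features centred but not scaled; each component's sign is
fixed so its largest-|loading| gene is positive, making coordinates
reproducible. The all-samples-identical corner returns zero coordinates
rather than an error.

## Differential expression

Normalisation is median-of-ratios: s_j = median_g count(g,j)/geomean_g over
genes with nonzero counts in every sample. Note this construction is
scale-invariant — multiplying *all* samples by a constant leaves every
factor unchanged, since the geometric-mean reference absorbs it — and
doubling one sample doubles exactly that factor.

Dispersion is estimated by moments on normalised counts with the variance
pooled within groups, α̂ = max(0, (s² − μ̄)/μ̄²), then shrunk toward a fitted
trend α(μ) = a₀ + a₁/μ with weight 0.7 by default: at three replicates the
per-gene estimate carries ~4 degrees of freedom while the trend pools
thousands of genes, so strong shrinkage is appropriate; the weight is an
argument. The trend is an ordinary least-squares fit on all finite raw
estimates; singular fits (all means equal) fall back to a flat trend.

Each group's mean is the average of normalised counts with
expected-information NB standard errors, se(log m) = √((1 + αm)/(n·m)); the
Wald statistic is log2FC/se against a normal reference. This
normalised-counts estimator was chosen over a per-sample-weighted GLM fit
deliberately: it depends on the data only through count/size-factor ratios,
which makes contrast antisymmetry and size-factor invariance *exact* rather
than approximate, at a negligible efficiency cost when size factors are
within ~±20% of one. A gene with an all-zero group is reported at a clamped
mean with an enormous standard error (hence p ≈ 1) rather than an infinite
fold change — a conservative convention worth knowing about: presence/
absence genes are not called. Genes whose normalised counts summed over the
contrast fall below 10 (matching the expressed-gene cutoff) are excluded
from the Benjamini--Hochberg multiplicity `m` and reported with missing
padj. Volcano classes use strict inequalities (padj < 0.05, |log2FC| > 1;
the curated tier at > 2); the network stage's DEG definition is non-strict
(|log2FC| ≥ 2), following the network-figure convention rather than the
volcano one.

## Enrichment

ORA uses the inclusive hypergeometric upper tail P(X ≥ k) with BH across
tested sets; sets smaller than 3 after intersection with the universe are
skipped. The background universe defaults to the expressed genes of the
contrasted groups — the testable-gene background — because an unstated
universe silently changes every p-value; it is an explicit argument.

GSEA ranks genes by Wald z by default (log2FC and signed −log10 p are
alternatives; ties break alphabetically). The running sum steps up by
|score|^p/Σ_hits|score|^p at members (p = 1, the classic weighted statistic)
and down by 1/(N − N_hits) otherwise; ES is the signed maximum deviation,
with an exact |max| = |min| tie resolved to the negative extreme. Nulls are
*gene-set permutations* (random same-size sets), not phenotype
permutations: with n = 3 per group only 10 distinct label splits exist, far
too few for a usable null — a documented divergence from the desktop
tool's default. NES = ES/mean(|null ES| of matching sign); the FDR q is the
sign-stratified pooled-null exceedance ratio clamped to [0, 1]; sets with
fewer than 10 same-sign null scores get q = 1 and a warning. The
significance gate is NES ≥ 1.5 with q ≤ 0.25. One calibration caveat is
inherent to the construction: because null sets are drawn from non-DE genes
while permutation nulls sample the whole ranked list (including the extreme
planted scores), null |NES| centres slightly below 1 (~0.83 under the
default scenario), comfortably inside the tested [0.8, 1.2] band.

## TF networks

Merging unions source tags over identical (tf, target) pairs, resolves
activation-vs-repression conflicts to `unknown` (counted), and flags
self-loops. The expression filter removes nodes below 10 raw counts summed
over the contrasted samples; a TF whose every target drops cascades out
automatically unless it survives as a target itself. The DEG-centered
subnetwork keeps DEGs plus TFs with ≥ 1 DEG target; *connectivity* is the
number of distinct DEG targets within that subnetwork (not global prior
degree — the DEG-centered reading of "highest downstream regulation
effects"; the global alternative would rank hub TFs regardless of
relevance). The top 30 TFs are master regulators; refinement keeps each
TF's top 10 targets by |log2FC| (ties by id) — both counts are arguments,
as the source procedure quantifies neither. Edge classes come from the
endpoints' DE directions: up/down from the target, `mixed` when both
endpoints are DEGs of opposite direction.

## qPCR

Technical duplicate wells are averaged per reaction (spreads > 0.5 cycles
flagged); ΔCt = Ct_gene − Ct_ref per replicate; ΔΔCt baselines against the
*mean* ΔCt of the reference group (per-replicate baselining would need a
pairing the plate layout does not guarantee). Fold changes are reported
both as the arithmetic mean ± SEM of per-replicate 2^−ΔΔCt^ (the plotted
form) and as the geometric form 2^−mean(ΔΔCt)^, which a group swap inverts
exactly and which supplies the sign for RNA-seq concordance. The t-test
runs on ΔCt values (approximately normal; folds are not), equal-variance
Student form by default with Welch as an option — the source names
Student's test but not its input scale, and ΔCt is the defensible choice.
Zero-variance-equal-mean degenerate input returns t = 0, p = 1 by
convention.

## Numerical and procedural choices

* Every generator seeds all randomness from `sim_config(seed)`; sub-stages
  derive fixed offsets so call order cannot change results. GSEA takes its
  own permutation seed.
* Result tables order deterministically (p then gene id; connectivity then
  TF id), so byte-identical reruns are testable.
* BH adjustment delegates to the standard step-up implementation. It is
  worth noting the step-up output is *not* idempotent in general
  ((0.1, 0.9) → (0.2, 0.9) → (0.4, 0.9)); all-tied outputs such as the
  classic (0.04, 0.04, 0.04, 0.04) are fixed points.
* Problem sizes in the tests and acceptance script — 2,000 genes, 201 sets
  with 1,000 permutations for the enrichment calibration, 20 seeded runs
  for master-regulator recovery — were chosen as the smallest sizes at
  which the planted effects and calibration bands are statistically
  unambiguous.

## Known limitations

The Wald test at n = 3 with moment dispersions is approximate; its null
p-values are close to uniform under the simulated conditions but no
finite-sample guarantee exists (no t-reference or dispersion-uncertainty
correction is applied). Genes expressed in only one group are not called
(see above). The FDR q for gene-set permutation inherits GSEA's known
conservatism/anticonservatism trade-offs and is not a BH-adjusted p. The
generator's single shared dispersion makes the trend fit nearly degenerate
by construction — convenient for testing, flattering for the shrinkage
estimator.

## The analysis workflow

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `08_report.R`) that run these stages end to end on the
default synthetic study, write tables, figures and per-stage manifests
(seed, configuration, md5 checksums) under `results/`, and finish with a
recovery scorecard comparing detected DE genes, enriched sets and the
top-ranked master regulator against the planted truth. They are thin
narrative wrappers; every computation they perform is an exported package
function covered by the test suite.
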