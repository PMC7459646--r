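---
title: "Methods and design of methylRRBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of methylRRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methylRRBS implements the downstream arm of an RRBS study: it consumes
per-CpG methylation calls (Bismark coverage files) and gene models, and
produces differentially methylated cytosines (DMCs) and genes (DMGs),
regional annotation, global-pattern QC and pathway enrichment. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic-data validation does and does not establish.

## The per-CpG model

At a united CpG, each sample contributes a methylated count and a coverage.
Counts are pooled within each group and the two-group comparison is a
binomial logistic regression of methylation state on the group indicator,
tested by the likelihood-ratio (deviance) chi-square with one degree of
freedom. Two facts shape the implementation:

* For a binomial GLM whose only covariate is a two-level factor, the
  maximum-likelihood fit is the per-group pooled proportion, so the deviance
  LRT depends on the data only through the pooled 2×2 table and equals the
  classical G statistic. `diffMeth()` therefore computes the test in this
  closed, vectorized form; `perSiteTest()` keeps the literal `stats::glm`
  route, and the test suite asserts agreement to 1e-8 in both directions.
  The LRT is preferred to the Wald test because it remains stable when a
  fitted proportion approaches the boundary.
* When a pooled group sits exactly at 0% or 100% (separation, where the MLE
  of the log-odds is infinite), the statistic is recomputed on the
  0.5-continuity-corrected pooled table and the site is flagged in the
  `corrected` column. This is deliberately conservative: such sites shrink
  toward the null rather than inflating the statistic.

The reported effect size Δ is the difference of count-pooled group
percentages (treatment − control), i.e. coverage-weighted, not the mean of
per-replicate percentages. Pooling uses all reads and keeps Δ consistent
with the tested model; replicate-averaging would weight a 5-read sample as
much as a 50-read one. No overdispersion correction is applied by default —
the test assumes binomial sampling within groups; see the generator section
for how this assumption is probed.

## SLIM q-values

Multiple testing is handled on the FDR scale with a sliding-linear-model
estimate of the null proportion π₀. The p-value CDF of a uniform-null plus
small-p signal mixture is, away from zero, a line of slope π₀. The estimator
evaluates the empirical CDF on a 100-point grid, fits a least-squares line
in each of 10 sliding windows spanning [0.1, 1] (window width half the
range), and takes the slope of the window with the smallest residual
standard error — the most linear stretch, which under signal is the one
least contaminated by the non-null mass. The slope is clamped to [0, 1] and
q-values are the step-up transform
q(i) = min over j ≥ i of π₀ · m · p(j) / j, so they are monotone in p and
bounded above by the Benjamini–Hochberg values. With fewer than 10 p-values
the grid is meaningless and the function falls back to plain BH (π₀ = 1)
with a warning. Discrete, conservative p-values (boundary sites) push mass
toward p = 1; this biases π₀ upward, never downward, so FDR control is not
undermined.

## DMC and DMG calling

A site is a DMC iff q < 0.01 (strict) and |Δ| ≥ 20 percentage points
(inclusive), hyper- or hypomethylated by the sign of Δ. A gene is a DMG iff
it carries at least one DMC in its gene body (exon, intron) or promoter
(P250, P1K, P6K). Flank DMCs are tallied per gene for reporting but do not
create DMGs; intergenic DMCs map to no gene. Contrasts are oriented
treatment:control with the control group stated explicitly (in the
three-group design: SS:NC and SO:NC with NC as control, SO:SS with SS as
control); swapping the labels negates every Δ and exchanges hyper/hypo while
leaving p and q unchanged, which the suite asserts.

## The region model

Canonical isoform selection keeps, per gene, the transcript with the longest
spliced sequence (sum of exon widths), breaking ties by the smallest
transcript identifier so the choice is deterministic. Promoter tiers are
placed upstream of the TSS — the standard promoter convention, and the one
that makes a 6001–10000 bp "flank from TSS" band coherent — mirroring
rightward in genomic coordinates for minus-strand genes, and truncated at
chromosome ends. Promoters of neighbouring genes are not truncated against
each other; collisions are resolved only at the CpG level by the precedence
exon > intron > P250 > P1K > P6K > flanks > intergenic, with equal-precedence
ties going to the lexicographically smallest gene id. Coordinates are
1-based inclusive GRanges throughout, matching both GFF3 and the Bismark
coverage dialect, so no conversion happens at I/O. The Bismark `.cov` format
carries no strand column; sites are indexed by position and imported
unstranded, and annotation ignores strand (a CpG's label does not depend on
which strand its call came from).

## Coverage filtering and uniting

Per sample, sites with coverage ≤ 10 reads or strictly above the sample's
own 99.9th coverage percentile are removed; the percentile is computed by
linear interpolation (type-7 quantile) on the raw, unfiltered distribution,
and both bounds are evaluated on that same distribution, so their order
cannot matter. Uniting intersects the retained site lists of every sample in
the contrast — no per-group relaxation — because the per-site test requires
counts in all samples. The optional FASTQ digestion filter trims reads to
50 bp and keeps those whose 5′ trinucleotide is in {CGG, TGG, CGA, TGA}:
MspI (C^CGG) and TaqI (T^CGA) fragment starts, with the bisulfite-converted
unmethylated variants. The signature set is configurable since digestion
chemistry details vary between protocols.

## Global patterns

Exploration runs on the percent-methylation matrix of united sites (not
logit-transformed, matching how methylation is reported). Site selection
keeps variances strictly above the chosen percentile (default 95; ties
excluded). PCA uses `stats::prcomp`; Ward clustering uses
`stats::hclust(method = "ward.D2")` on Euclidean distances, the form of
Ward's criterion consistent with squared Euclidean geometry. t-SNE is
implemented in-package as an exact (non-Barnes-Hut) algorithm — perplexity
calibration by bisection, early exaggeration ×12 for 100 iterations,
momentum gradient descent for 1000 iterations — because sample counts in
RRBS designs are tens at most, where the exact gradient is trivial and
reproducibility under a seed is the only hard requirement. Perplexity must
satisfy p < (n−1)/3; the default 2 suits a 12-sample design. On weak-effect
designs the package asserts only seed-reproducibility of embeddings, not
cluster separation: with realistic effect sizes, individual variation can
legitimately dominate group structure, and a QC plot that fails to separate
groups is a finding, not a bug.

## Enrichment

All three procedures run per region scope (each label plus "all") with
Benjamini–Hochberg adjustment within a scope:

* **ORA** — hypergeometric upper tail of the DMG/pathway overlap. The
  universe is the set of genes with at least one united CpG (configurable):
  only assayed genes can become DMGs, and a whole-genome universe would
  overstate enrichment.
* **Wilcoxon** — signed-rank test pairing the two pooled group means at
  every site in the pathway's genes. Pairing is per site (not per gene):
  sites are the sampling units that carry the methylation signal, and
  per-gene averaging would discard the within-gene pattern. Pathways with
  fewer than 5 usable sites, or with all-zero differences (the statistic is
  undefined), are reported NA and excluded from the adjustment.
* **KS-boot** — sup-norm ECDF distance between the pathway's Δ values and
  the scoped background, with a null built from 1000 size-matched
  with-replacement draws from that background, and
  p = (1 + #{D ≥ D_obs}) / (1001). The add-one estimator avoids p = 0 and
  makes 1/1001 the attainable minimum; the statistic is evaluated at the
  jump points of both step functions, and the test suite checks it against
  `stats::ks.test` on tie-free data and checks null calibration by
  simulation.

## The synthetic-data generator

The generator is the package's study-condition stand-in: three groups
(NC, SS, SO) × 4 samples, ~30× mean coverage, negative-binomial coverage
variation, per-site baseline methylation from a bimodal Beta(0.8, 0.8) (CpG
methylation in vertebrate tissues concentrates near 0 and 1), and planted
effects of 30 percentage points, half hyper / half hypo, on 500 of the
sites. Where a site's baseline cannot absorb the assigned direction without
clipping, the direction is reflected so the planted |Δ| always equals the
nominal effect size; the truth table records the realized direction and
difference. Methylated counts are beta-binomial with intra-class correlation
ρ; the default ρ = 0 yields binomial counts — the sampling model the
per-site test assumes — so null calibration and recovery are evaluated under
the test's own assumptions, while ρ > 0 is exposed to probe robustness to
biological overdispersion (under which the uncorrected LRT is expected to be
anti-conservative; that behaviour is documented, not asserted).

What the generator does not emulate: linked methylation of neighbouring
CpGs, strand-split calls, bisulfite conversion failure, SNP interference,
CpG-density enrichment of real RRBS libraries, or mapping artefacts.
Passing the validation therefore shows the machinery is correct under its
stated model, not that real-data effect sizes will be recovered at these
rates.

## Validation scales and numerical details

The test suite and `scripts/acceptance.R` exercise: the DMC rule on a
constructed 4-site table; glm-vs-closed-form agreement on 1000 single-
replicate sites; null calibration and SLIM π₀ on 10,000-site 4-vs-4
contrasts over 5 seeds; recovery of 500 planted 30-point effects among
10,000 sites; annotation against a brute-force all-overlaps precedence
oracle on 20 toy genomes × 10,000 random positions; KS-boot calibration on
500 null pathways of 30 sites at 1000 iterations; ORA against combinatorial
enumeration on N = 100, K = 10, n = 20; and byte-identical pipeline reruns.
These sizes were chosen to give tight Monte-Carlo bounds while keeping a
full run in minutes on one core.

Remaining numerical conventions, collected: percentile computations use
type-7 (linear interpolation) quantiles; the coverage filter's upper rule is
strict ("above"), the lower rule inclusive ("≤ 10"); variance selection is
strict; q-threshold strict, Δ-threshold inclusive; isoform and annotation
ties break lexicographically; empty inputs error early with named messages
rather than propagating NAs.

## Limitations

Single-CpG testing ignores spatial correlation along the genome (no DMR
segmentation or tiling); covariates beyond the group factor are not
supported; the beta-binomial flag exists in the generator but the test
itself applies no overdispersion correction; GO-style ontology propagation
is out of scope (a GO mapping table is treated like any other gene-set
table); and enriched-pathway counts depend on the pathway database version,
so they are reported, never asserted.
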