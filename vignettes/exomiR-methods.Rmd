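---
title: "Moderated permutation statistics for small exosomal miRNA cohorts"
author: "exomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated permutation statistics for small exosomal miRNA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomiR)
```

## The problem

Multiplexed bead arrays can profile a few hundred miRNAs simultaneously in
postmortem brain tissue, but psychiatric brain-bank cohorts are tiny: the
design this package targets has 6 controls (C), 6 bipolar disorder (BD) and
8 schizophrenia (SZ) samples over a 312-miRNA panel. At that size, ordinary
per-feature t-tests reward miRNAs whose standard errors are accidentally
small, and multiplicity control has to come from permutations rather than
parametric tails. `exomiR` implements the complete analysis stack for this
situation:

1. preprocessing of raw bead-array exports (background flooring,
   median-of-positives normalization, informativeness filtering, cube-root
   transform),
2. a moderated multiclass z-score with an exchangeability constant,
   permutation q-values and a windowed local false discovery rate,
3. Holm step-down correction and an exact Wilcoxon rank-sum supplement,
4. centroid-correlation hierarchical clustering of samples,
5. nearest-shrunken-centroid (NSC) classification with cross-validated
   misclassification curves,
6. medication drug-class covariate adjustment by z-score subtraction, and
7. qPCR delta-CT validation against a stable reference miRNA.

A seeded synthetic-data generator with a machine-readable truth table makes
every stage testable without instrument data.

## The moderated multiclass score

For miRNA $i$ and diagnostic group $k$ with group sizes $n_k$,
$N = \sum_k n_k$ and $K$ groups,

$$z_{ik} = \frac{\bar x_{ik} - \bar x_i}{s_i + s_0}, \qquad
s_i = \sqrt{\frac{\sum_k \sum_{j \in k} (x_{ijk} - \bar x_{ik})^2}{N - K}
\cdot \frac{1}{N}},$$

where $\bar x_{ik}$ is the group mean, $\bar x_i$ the grand mean and $s_0$
a single exchangeability constant shared by all miRNAs. Because the
group-size-weighted group means average to the grand mean, the identity
$\sum_k n_k z_{ik} = 0$ holds exactly for every miRNA — a structural
invariant the test suite checks both on generated data (to $10^{-6}$) and
on the packaged published score table (to print precision, $\le 0.05$).
The $1/N$ factor puts $s_i$ on a standard-error footing so the scores land
on the familiar low-single-digit z range. Rows are ranked by
$D_i = \max_k |z_{ik}|$, which reproduces the ordering of the published
three-group table; the scalar used there was never disclosed, so this is a
documented inference, not a reconstruction.

$s_0$ is chosen by scanning the percentiles $0, 5, \dots, 100$ of the
$s_i$ distribution and minimizing the coefficient of variation of the
median ranking statistic across ten quantile bins of $s_i$. This is the
device that stops low-scale miRNAs from floating to the top of the
ranking; on a null panel it demonstrably thins the $|z| > 3$ tail relative
to $s_0 = 0$.

## Permutation q-values and the identity assignment

The null distribution recomputes $z$ and $D$ under group-label
permutations that preserve the group sizes, holding $s_0$ fixed
(B = 1000 by default; full enumeration when the design admits at most 500
distinct assignments). Under enumeration the identity assignment is
excluded: the null should contain genuine rearrangements only, otherwise
an observed statistic could never exceed "every null value" no matter how
strong the signal.

For the miRNA of rank $r$,

$$q_{(r)} = 100 \cdot
\frac{\mathbb{E}_b\,\#\{(b, j) : D^{\text{null}}_{bj} \ge D_{(r)}\}}{r},$$

made non-decreasing along the ranking by a running maximum and clipped to
$[0, 100]$. The numerator is the **mean** per-permutation exceedance count
— the expected number of false positives at the threshold. An alternative
is the per-permutation **median** count (`center = "median"` in
`samQvalues()`), but the median has a structural defect at the top of the
ranking: on null data the observed maximum statistic is exchangeable with
the per-permutation maxima, so the median count at rank 1 is zero with
probability about one half, and roughly every second null dataset would
flag its top miRNA at $q = 0\%$. With the mean, a $q = 0\%$ call requires
the observed statistic to exceed *every* null value in *every*
permutation, which on null data happens with probability about
$1/(B + 1)$. The package therefore uses the mean by default; the
calibration tests (20 seeded null cohorts, zero $q = 0\%$ calls) pin this
behavior down.

The windowed local FDR judges a miRNA together with its neighbors in the
ranking: for rank $r$ the window spans ranks $[r - w/2,\, r + w/2]$
(default $w = 50$, clipped at the list ends), and the local FDR is the
mean null count inside the D-interval spanned by the window, divided by
the observed count in it, again in percent and clipped to $[0, 100]$. On
null panels it sits near 100% through the middle ranks; a top block of
strongly shifted miRNAs drives it toward 0. Note the estimator's
granularity: a *single* strong outlier cannot pull its window below
roughly $(w/2 - 1)/(w/2)$, because the window also spans its null-ish
neighbors — small local FDR at the top requires the window to be filled
with signal.

## Synthetic cohorts: what they emulate and what they do not

`simConfig()` freezes the study conditions: 312 miRNAs, groups
C/BD/SZ = 6/6/8, per-miRNA baselines $b_i \sim N(6, 1.5^2)$ on the log2
scale, measurement noise $\sigma = 0.2$ (log2), 20 spiked miRNAs shifted
by +2 log2 in SZ, and a background constant of 30 subtracted from the
linear intensities so that low-abundance readings are exported as
negative numbers — exactly the artifact the flooring stage
(`floorNegatives()`) exists for. The effect and noise values are the ones
the analysis-level property checks are stated at; the baseline and
background were chosen once to give a realistic sub-background fraction
(about a fifth of the panel) and were not revisited. A single seed drives
every sub-generator through fixed offsets, so outputs are byte-identical
under a fixed seed.

Deliberate simplifications: Gaussian log2 noise with a common variance
(no mean–variance trend, no bead-count heteroscedasticity), independent
miRNAs (no co-expression), additive log2 effects, no batch or
plate-position structure on the array side. Passing tests on these
cohorts therefore demonstrate that the *procedures* are correct and
calibrated, not that the instrument's error model is captured.

Two interactions between the generator and the statistics are worth
knowing. First, background censoring can floor a low-abundance spiked row
to all zeros, in which case no score can recover it; the
parameter-recovery test disables censoring because it is a property of
the censoring stage, not of the score engine. Second, a uniform log2
shift of *all* spiked miRNAs in *one* group rescales that group's
profiles by a constant — and the clustering distance
$2(1 - \mathrm{cc})$ is blind to rescaling, because Pearson correlation
is scale-invariant. Group separation in correlation clustering requires a
heterogeneous signature (different miRNAs shifted in different groups or
directions), which is also what the published q-zero list looks like: it
mixes positive and negative group scores. The clade-structure checks
therefore spike all three groups (7/7/6 at +3 log2).

## Preprocessing choices

* **Flooring**: negative raw readings mean "below background", are set to
  0 and flagged; the flag travels with the object as a `floored` assay.
* **Normalization**: each sample is rescaled so its median *positive*
  value matches the global median of per-sample medians. Zeros are
  excluded from the statistics — they encode absence, not abundance —
  and stay exactly zero. The operation is idempotent and removes
  per-sample scalar gains; the instrument vendor's exact intra-plate
  procedure is not public, so this is a documented stand-in and can be
  skipped.
* **Informativeness filter**: keep miRNAs positive in at least 3 samples
  (the same "at least three" count the covariate eligibility rule uses)
  with nonzero variance. The published 312-to-198 narrowing was
  attributed to an undisclosed regression model; rather than guess it,
  the filter is explicit and parameterized.
* **Cube root**: the variance-taming transform applied before
  correlation clustering; monotone, exact at 0.

## Clustering and classification

Clustering is greedy agglomeration under
$d = 2(1 - \mathrm{cc})$, where $\mathrm{cc}$ is the Pearson correlation
between cube-root profiles and cluster *average* profiles
(centroid-correlation linkage, following the method's own description,
not average linkage of pairwise distances). $\mathrm{cc}$ is clamped
below at 0 so the dendrogram lives on the stated $[0, 2]$ scale — raw
Pearson correlation can be negative, and clamping reconciles the formula
with the scale. Centroid linkage can invert, so merge heights are made
monotone by a running maximum. Ties are broken by the lexicographically
smallest pair of leading sample ids, making the tree deterministic.
Export goes through `hclust`/`ape` (Newick with the usual half-height
branch lengths) and a plain merge table.

NSC uses the standard construction
$d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/N}$, soft-thresholding
$d'_{ik} = \mathrm{sign}(d_{ik}) \max(|d_{ik}| - \Delta, 0)$, and
shrunken centroids rebuilt from $d'_{ik}$. Priors are uniform (class
sizes 6/6/8 are near-equal; configurable). Cross-validation is
leave-one-out by default, appropriate at $N = 20$; k-fold is available.
Discriminant ties — inevitable at full shrinkage with uniform priors —
go to the class with the largest training count, so the fully shrunken
classifier predicts the majority class and its LOO error equals the
majority-class error exactly (12/20 on the study design). One caveat
learned from the null checks: LOO error of an unshrunk NSC under
permuted labels is *worse* than chance (about 0.9), a well-known
leave-one-out artifact — the held-out sample's removal pushes its own
class centroid away. "No predictive power under the null" is therefore
assessed at the classifier's best threshold: even the minimum of the LOO
curve stays within 0.15 of the majority-class error.

## Medication covariates

Seven drug classes A–G are defined by mechanism. A class is usable as a
covariate only when at least three case subjects take it and at least
three do not — with fewer, the standard error underlying the effect score
is meaningless. Eligibility is judged *within the diagnostic groups the
class is prescribed in* (A: SZ; B, C: BD and SZ; D, E, F: BD; G: SZ;
controls take none of the listed medications and are never counted):
pooling all cases would, for example, declare the BD-only mood-stabilizer
class eligible by counting SZ subjects who would never receive it as
"non-takers". On the packaged 20-sample cohort this yields exactly
classes A, B and C as usable covariates.

The effect score of a class is the taker-group moderated z from rerunning
the two-class engine on takers versus non-takers; adjustment subtracts
the requested classes' effects from the disease z-scores in exact
arithmetic, with blank (never-computed) effects contributing zero, and
combined classes subtracting the sum of the individual effects. The test
suite replays the full published ledger: every non-blank effect cell
against every adjusted-score column agrees within $10^{-4}$ (print
precision). The BD-side published adjustment table is shipped verbatim
for reference but is not used for arithmetic checks, because several of
its printed columns are internally misaligned. P-values attached to
adjusted scores are two-sided permutation tail probabilities with
add-one smoothing ($p \ge 1/(B+1)$); the published adjusted tables'
p-value convention matches no standard distribution we could identify,
so no attempt is made to reproduce those printed p-values digit for
digit.

A limitation worth stating plainly: score subtraction is a crude
adjustment. When the medication assignment only partially overlaps a
diagnostic group, the taker-contrast score and the disease score live on
different effective scales (the drug effect inflates the within-group
variance of the disease design but not of the taker design), and
subtraction can overshoot. The confound-removal property test uses an
assignment aligned with the group — the regime in which subtraction is
well-behaved; partial-overlap confounds are flagged as a caveat, not
solved.

## qPCR validation

Wells carry (sample, target, plate, replicate, CT). Within each plate,
replicate CTs are averaged per target and the reference's average is
subtracted (the reference is a stably expressed miRNA; miR-423 in the
assay mirrored here). Per-plate delta-CTs are averaged unweighted across
plates ("average CT" semantics), per-plate additive offsets cancel by
construction, and group contrasts use a two-sided pooled-variance
Student's t-test (Welch by flag; the published analysis did not say
which, pooled is the default). Fold change is the Livak relation
$2^{-\Delta\Delta CT}$ with case-minus-control sign, so increased
expression in cases gives fold > 1. The generator's amplification model
is $CT = 35 - \log_2(\text{expression} + 1) + \text{plate offset} +
N(0, 0.3^2)$; end-to-end recovery of a 2.77-fold effect at the study's
sample sizes is accurate to about 1% in the median over 50 cohorts.

## Problem sizes and numerical notes

The shipped checks run the score engine at B = 1000 permutations on
312-miRNA, 20-sample cohorts (about 1.5 s per cohort), 20 null cohorts
and 10 spiked cohorts for calibration and recovery, 50 cohorts for qPCR
recovery, and 20 for the permuted-label classification bound; these
sizes were chosen to make the binary pass/fail properties stable across
seeds. Degenerate inputs are handled explicitly: all-zero samples are a
normalization error naming the sample; a panel with all-zero scales is a
degeneracy error in $s_0$ selection; constant miRNAs score 0; zero-variance
profiles in clustering get correlation 0 (distance 2) with a warning;
Wilcoxon p-values are exact mid-rank enumerations (identical inputs give
p = 1), with a tie-corrected normal approximation only beyond 200,000
assignments.
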