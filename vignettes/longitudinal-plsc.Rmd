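---
title: "Longitudinal PLS correlation for seed-based connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal PLS correlation for seed-based connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem this package addresses

Developmental neuroimaging cohorts are rarely clean panel designs. A
typical clinical cohort mixes purely cross-sectional participants with
participants scanned two, three or four times, at irregular intervals,
over an age span that can run from childhood into adulthood. The
scientific questions — does a patient group differ from controls in
seed-based functional connectivity, and does the *maturation* of that
connectivity differ — involve group effects, age effects, and their
interactions, measured over tens of thousands of voxels at once.

`longplsc` implements a multivariate approach to this setting: partial
least squares correlation (PLS-C) between a block of design variables
encoding group and longitudinal age structure and a block of seed-based
connectivity maps, with resampling inference that respects the
within-subject dependence of repeated scans. The surrounding stages —
probabilistic-atlas ROI masks, seed-to-voxel Pearson maps, motion
summaries and censoring, voxelwise confound regression — are included so
that the whole path from 4D images and a cohort table to thresholded
stability maps is reproducible and testable.

# The model

## Blocks

For scans $i = 1, \dots, n$ (a subject contributes one row per scan):

* $X$ ($n \times p$): seed-to-voxel Pearson correlation values inside a
  brain mask, one column per voxel, after voxelwise residualization of
  confounds and column z-scoring.
* $Y$ ($n \times q$): design variables, z-scored. The default encoding
  has $q = 5$ columns: group ($\pm 1$), cross-sectional age,
  longitudinal age, and the two group-by-age interactions.

The longitudinal age decomposition is the standard between/within split:
for a scan of subject $s$ at age $a$,
$\mathrm{age}_{cs} = \bar a_s$ (the subject's mean age over their
visits) and $\mathrm{age}_{long} = a - \bar a_s$. The two components
reconstruct age exactly, the within component sums to zero inside every
subject, and a single-visit subject contributes
$\mathrm{age}_{long} = 0$. This makes the design well defined for an
arbitrary mixture of cross-sectional and longitudinal participants: each
subject simply contributes as many rows as they have scans.

## Decomposition

PLS-C decomposes the cross-covariance of the two blocks,

$$R = Y^\top X, \qquad R = U S V^\top,$$

into latent components: design saliences $U_k$ (unit-norm weights over
design variables), brain saliences $V_k$ (unit-norm weights over
voxels) and singular values $S_k$ measuring the cross-covariance
captured by the pair. Brain scores $L_X = XV$ express, per scan, the
expression of each multivariate brain pattern; design scores
$L_Y = YU$ are the matching projections of the design. With both blocks
z-scored by the population (divide-by-$n$) convention, the population
covariance of $(L_{X,k}, L_{Y,k})$ equals $S_k / n$.

## Inference

**Permutation test.** Significance of each component is assessed
against a null distribution of singular values obtained by permuting
the correspondence between design and brain data, with the add-one
estimator $p_k = (1 + \#\{S^{null}_k \ge S_k\}) / (1 + n_{perm})$,
which can never return zero. Because repeated scans of one subject are
strongly dependent, the default scheme permutes *subject blocks*: all
scans of a subject move together, and blocks are exchanged only among
subjects with the same scan count, so every permuted design block has
the correct length and no scan is ever separated from its subject. A
naive scan-level scheme is available for comparison; it is
anticonservative in longitudinal data and not the default. Subjects in
singleton strata (a scan count no other subject has) are necessarily
fixed points; they are reported, not an error.

**Bootstrap stability.** The reliability of each voxel's contribution
is assessed by resampling *subjects* (never scans) with replacement,
recomputing the SVD per replicate, and aligning replicate components to
the original by sign (flip a replicate pair $(U_k, V_k)$ jointly when
the dot product of its $V_k$ with the original is negative). The
bootstrap ratio (BSR) of voxel $j$ on component $k$ is the mean of its
salience over replicates divided by the population SD over replicates.
Under an approximately normal bootstrap distribution, $|BSR| > 3$
corresponds to a 99% confidence interval excluding zero; thresholding
retains exactly those voxels (strict inequality), preserving the sign
so increased and decreased connectivity remain distinguishable.

# Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| mask threshold | 0.5 | probability | strict `>`; max-probability assignment on top |
| FD head radius | 50 | mm | standard spherical-head convention |
| FD censoring cutoff | 0.5 | mm | exposed as config; scrubbing conventions vary between labs |
| min surviving frames | 100 | frames | below this the scan is flagged excluded, not truncated |
| `n_perm` | 1000 | — | conventional; add-one p-values are then bounded below by 1/1001 |
| `n_boot` | 500 | — | conventional; 200 is adequate for BSR screening at desk scale |
| BSR cutoff | 3 | — | approximately a 99% CI excluding zero |
| group coding | +1/−1 | — | keeps interaction columns centered under balance |

Confounds (default: sex, full-scale IQ, mean post-censoring FD) are
removed per voxel by OLS with intercept before PLS-C; residuals are
orthogonal to every confound column by construction. Two-level factor
confounds are coded $\pm 1$; numeric confounds are used as given, since
affine rescaling of a regressor does not change OLS residuals. Note
that when a confound is correlated with the grouping (IQ typically is,
in clinical developmental cohorts), residualizing it also removes
shared group variance — this is the intended, conservative behavior,
and it visibly attenuates planted group effects in the synthetic demo.

# Numerical choices

* **Sign conventions.** An SVD is sign-ambiguous per component. For
  reproducibility across linear-algebra backends, each $(U_k, V_k)$
  pair is flipped so that the largest-magnitude entry of $U_k$ is
  positive. Bootstrap replicates are aligned to the original solution
  by the sign of $V_k^\top V_k^{orig}$; this is adequate for
  well-separated components and is a documented limitation for
  near-degenerate spectra (no Procrustes rotation is applied, in either
  the bootstrap or the permutation null — the null compares the
  $k$-th sorted permuted singular value to the $k$-th observed one).
* **Ties.** Exact probability ties at a voxel's maximum are assigned to
  the lexicographically first label name, deterministically.
* **Standardization.** All z-scoring uses the population
  (divide-by-$n$) variance, so that score covariances relate to
  singular values exactly as $S_k/n$.
* **Degenerate cases.** Zero-variance voxels yield missing connectivity
  values and are removed from the mask for all scans. Zero-variance
  design columns (e.g. longitudinal age in a purely cross-sectional
  cohort) are dropped with a warning. Bootstrap replicates whose
  resampled design loses a column to zero variance are redrawn, up to a
  cap. Voxels with zero bootstrap SD are flagged degenerate rather than
  divided; when their mean salience is nonzero they are reported stable
  (they are identical in every replicate).
* **p-values.** Add-one counting; $p \ge 1/(n_{perm}+1)$ always.

# Design choices where the design was open

* **Age encoding** is pluggable (`age_strategy`), with subject-mean
  centering as the default because it is the standard between/within
  decomposition for unbalanced repeated measures and degrades
  gracefully to cross-sectional data. Interactions are formed from
  unstandardized components and all columns are z-scored afterwards.
* **Permutation scheme.** The subject-block principle is stated in the
  literature mainly for bootstrap resampling; we apply it to the
  permutation null as well, as the conservative reading for dependent
  rows, and keep scan-level permutation available for comparison.
* **BSR numerator.** The bootstrap mean (not the original salience) is
  divided by the bootstrap SD, implementing the common "mean of the
  bootstrap distribution over its SD" definition literally. With
  well-separated components the two numerators differ negligibly.
* **Raw correlations.** Connectivity maps are stored as raw Pearson r
  by default; a Fisher-z flag exists but is off, so downstream results
  correspond to the map values most pipelines report.

# What the synthetic generator emulates — and what it does not

`generate_cohort()` produces a two-group developmental cohort: baseline
ages uniform on 5–30 years, 1–4 visits per subject (defaults weighted
so roughly 40% of subjects return), inter-visit gaps near 1.5 years,
balanced sex, group-shifted IQ (means 72 vs 110.7, SDs ≈ 13) and
group-shifted motion (mean FD 0.18 vs 0.14 mm, SD 0.06), and integer
clinical subscale scores (0–6) for the case group with a configurable
prevalence of subjects ever reaching the conventional cutoff of 3.
These defaults mirror the structure of a real mixed
longitudinal/cross-sectional clinical cohort of about a hundred
subjects per arm.

`generate_feature_data()` plants latent structure directly at the level
the model assumes: $X = \sum_k e_k\, z(y_k)\, V_k^\top + \varepsilon$,
where $y_k$ is a named design column, $z$ the population z-score and
$V_k$ a unit-norm voxel pattern, so the effect size $e_k$ *is* the
covariance between the design column and the latent brain score. This
makes analytic sanity checks possible (noise-free recovery is exact)
but means the generator emulates the *statistical* contract of
connectivity maps, not their physiology: no hemodynamics, no
physiological noise, no scanner drift, and — unless the smoothed-noise
mode is enabled — no spatial autocorrelation. Passing tests therefore
demonstrate the estimator's correctness and calibration under the
stated model, not performance on real BOLD data.

`generate_toy_timeseries()` builds small 4D volumes whose regions share
latent signals with a requested correlation matrix, an atlas whose
probabilities peak in the true regions, and a motion trace with
translation spikes at chosen frames, so the image-level modules (masks,
seed maps, FD, censoring) are exercised end to end through the same
NIfTI I/O path used for real data.

# Problem sizes used by the test suite

The package's checks run at desk scale, chosen to keep the full suite
fast while leaving clear statistical margins: SVD/oracle agreement on
5 × 2000 blocks; rank-1 recovery at 120 scans × 5000 voxels with a
planted covariance of 20 (recovery cosine ≈ 0.94 at noise SD 1);
permutation calibration over 200 null datasets of 40 subjects each with
200 subject-block permutations; bootstrap stability with 200 replicates
(500 remains the recommended default for real analyses); block
integrity audited exhaustively over every stored replicate of toy
cohorts.

# Known limitations

* Preprocessing (realignment, normalization, nuisance time-course
  regression, template construction) is out of scope; inputs are
  assumed preprocessed and co-registered to a common analysis grid.
* The permutation null treats the $k$-th sorted permuted singular value
  as the reference for component $k$; for $k > 1$ this is known to be
  conservative when earlier components are strong.
* Sign alignment by dot product can mis-align bootstrap replicates when
  two singular values nearly coincide; BSR maps for such components
  should be read with caution.
* Subjects whose scan count is unique in the cohort cannot move under
  stratified block permutation; with very heterogeneous visit
  structures this reduces the effective number of permutations.
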