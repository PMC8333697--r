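---
title: "Voxel-wise degree centrality, seed connectivity and MVPA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise degree centrality, seed connectivity and MVPA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`netdc` implements a complete resting-state fMRI connectome analysis
chain of the kind used in clinical case-control studies:

1. **Temporal preprocessing** — drop initial volumes, per-voxel linear
   detrend, nuisance regression, zero-phase band-pass filtering
   (0.01–0.08 Hz), Gaussian spatial smoothing.
2. **Binarized degree centrality (DC)** — for every gray-matter voxel,
   the number of other gray-matter voxels whose time-course Pearson
   correlation exceeds r = 0.25; z-scored against the gray-matter mean
   and SD and then spatially smoothed.
3. **Seed-based functional connectivity (FC)** — Fisher r-to-z maps of
   the correlation between a seed's mean time course and every voxel,
   with seeds taken from the significant DC clusters.
4. **Group inference** — voxel-wise OLS with a group indicator and
   age/sex/education covariates; two-sided cluster forming at
   p < 0.001; cluster-level FDR via group-label permutation and
   Benjamini–Hochberg at q < 0.05.
5. **Clinical association** — per-subject cluster means correlated with
   disease-activity (SLEDAI), cognition (MoCA) and depression (BDI-II)
   scores in the patient group.
6. **MVPA** — linear soft-margin SVM on the smoothed DC z-maps,
   leave-one-per-group-out cross-validation, permutation significance,
   ROC/AUC, and weight-map localization of the top 20% |weight| voxels.

Because raw clinical imaging data of this kind are rarely shareable, the
package ships a synthetic cohort generator (`generate_cohort()`) that
plants a known hub-connectivity group difference, giving every stage a
recoverable ground truth. The test suite validates the chain against
that ground truth and against exactly recomputable worked examples.

# The synthetic cohort model

Each subject's 4D series on a small grid (default 16³, 3 mm isotropic)
is

$$ y_v(t) \;=\; \sum_{k=1}^{K} L_{vk}\, s_k(t) \;+\; b_v\,\tau(t) \;+\; \varepsilon_v(t), $$

where the $s_k$ are $K = 4$ latent network signals (white noise
band-passed to 0.01–0.08 Hz and standardized), $L$ is a voxel-by-network
loading matrix, $b_v \sim N(0, 0.5^2)$ is a linear drift slope over the
scan ($\tau$ runs from −1 to 1), and $\varepsilon_v(t) \sim N(0,
0.6^2)$ is white noise. Gray matter is the grid interior (a one-voxel
border models non-brain). Each non-hub voxel loads 1 on the network of
its spatial octant. A central cubic **hub region** (default 4³ voxels)
loads $a$ on two of the four networks; in patients
$a = a_0 + \delta + \eta_i$ with $a_0 = 0.02$, $\delta = 0.9$, and a
per-subject jitter $\eta_i \sim N(0, 0.05^2)$ ("hub strength"), while
controls have $a = a_0 + \eta_i$.

Cohort defaults mirror a typical clinical resting-state design: 47
subjects per group, 240 volumes at TR = 2 s, with grids reduced to
desk scale (≤ 24³ enforced). Phenotypes are truncated normals with
means/SDs typical of a young, predominantly female lupus cohort
(≈ 1:4 male:female), and MoCA/SLEDAI can be linearly coupled to hub
strength (`default_covariate_model(moca_coupling = ...)`) so that
correlation recovery is testable. Every output is a pure function of
the `cohort_spec`: one RNG stream is derived per subject from the
master seed and a subject counter, so subject 1 is bit-identical
regardless of cohort size.

## Why these loading values

A hub voxel with loading $a$ on $m$ networks has population correlation

$$ r(a) \;=\; \frac{a}{\sqrt{m a^2 + \sigma^2}\,\sqrt{1 + \sigma^2}} $$

with a voxel of one of those networks, which saturates at
$1/(\sqrt{m}\sqrt{1+\sigma^2})$ — about 0.35 if the hub loads on all
four networks ($\sigma = 1$), i.e. barely above the DC threshold of
0.25. Two further facts shape the defaults:

* **Band-limiting caps the effective temporal degrees of freedom.**
  After 0.01–0.08 Hz filtering at TR = 2 s, a 240-volume series carries
  roughly 60 effective samples, so the sampling SD of a voxel-pair
  correlation is ≈ 0.12 *however long the series*.
* **Correlation draws are shared.** All pairs between one hub voxel and
  one network move together with that network's realization, so a group
  whose hub correlation sits near the threshold shows large, shared
  between-subject swings in hub degree.

The defaults therefore couple the hub to only $m = 2$ of the networks
(raising the saturation cap to ≈ 0.61 at $\sigma = 0.6$) and place
*both* groups in the flat tails of the sampling distribution: control
hubs at $r \approx 0.03$ and patient hubs at $r \approx 0.55$. The
planted effect is thus categorical — patient hub voxels couple broadly,
control hub voxels essentially not at all — which is deliberately
*stronger* than the graded hub differences expected in real patients.
Recovery tests passing under these conditions show that the chain
detects a clearly planted effect at realistic noise levels; they do not
show that real effects of this size exist.

# Preprocessing decisions

* **Order**: drop → detrend → nuisance regression → band-pass. Series
  feeding DC are *not* spatially smoothed (the DC z-map is smoothed
  instead); series feeding seed-FC are smoothed before connectivity.
  The nuisance-then-filter order is a documented package choice; the
  widely used toolboxes do not all agree and the difference is small
  when the nuisance series are themselves slow.
* **Filter**: order-5 Butterworth, applied forward and backward
  (zero-phase) so that filtering cannot shift temporal alignment and
  thereby distort correlations. Each voxel's temporal mean is removed
  before filtering — 0 Hz lies outside any admissible band, and this
  prevents a large offset from leaking an end transient through the
  zero-padded reverse pass. Transfer behavior is pinned by single-tone
  tests (0.04 Hz preserved within 5%; 0.2 Hz attenuated below 5%).
* **Smoothing**: separable Gaussian with σ = FWHM/(2√(2 ln 2)) per axis
  in mm (voxel sizes from the affine), kernel support 3σ, unit-sum
  taps, and reflection boundaries — constants are preserved exactly and
  small synthetic grids show no edge darkening.
* **Head motion**: realignment is upstream of this package (synthetic
  data are born aligned). The conventional exclusion limits (2.5 mm /
  2.5°) are carried as configuration metadata and applied only through
  the phenotype `include_flag`.

# Connectome decisions

* **Strict positive threshold.** DC counts voxels with r strictly
  greater than 0.25; negative correlations never count by default
  (`positive_only = FALSE` switches to |r|). Binary (unweighted) degree
  is the default, matching the binarized-map convention.
* **z-scoring convention.** The DC z-map uses the population (divide by
  n) SD. The map is a within-subject normalization, not an inferential
  statistic; the convention is pinned by a closed-form three-voxel test
  ([−1.2247, 0, 1.2247]).
* **Fisher z clipping.** r = ±1 maps to atanh(±(1 − 1e−7)) so FC maps
  stay finite.
* **Blockwise equality contract.** DC is computed blockwise against the
  standardized voxel matrix; the result must equal (and is tested
  against) a brute-force O(V²) pairwise oracle exactly, so chunk size
  can never change output.
* **Full-length series** are correlated (no windowing).

# Group inference decisions

* **Cluster-level FDR mechanism.** "Cluster-level FDR" names a
  correction, not an algorithm; the package realizes it as
  permutation-derived cluster p-values plus Benjamini–Hochberg. Each
  observed cluster's p is the proportion of group-label permutations
  whose maximum same-sign cluster extent (at the same forming
  threshold) reaches the observed extent, with the add-one convention
  (b+1)/(B+1). This is distribution-free and testable by calibration;
  a parametric random-field correction is out of scope.
* **Permutations shuffle the group label only**, keeping each subject's
  covariates attached to their map (a Freedman–Lane variant is a
  possible extension, not implemented).
* **Connectivity** defaults to 26-neighborhood (faces + edges +
  corners), switchable to 6 or 18; a hand-built toy with two diagonal
  blobs pins both behaviors (2 clusters under 6, 1 under 26).
* **Two-sided forming threshold with sign-split clusters**, since both
  increases and decreases are of interest.
* **Deterministic labels and peaks**: clusters are numbered by
  descending extent (ties: smallest linear voxel index); the peak is
  the max-|t| voxel (same tie rule) mapped through the affine with
  0-based indices to world mm.
* **Demographics**: pooled-variance (not Welch) two-sample t, computable
  from (mean, SD, n) summaries; 2×2 chi-square with Yates continuity
  correction for sex; Kolmogorov–Smirnov normality flags computed on
  standardized values (a descriptive flag, not a gate).

# MVPA decisions

* **C = 1** linear soft-margin SVM (libsvm via e1071); the
  regularization constant is exposed in the configuration and recorded
  in provenance. No feature scaling by default — DC z-maps are already
  within-subject normalized; a train-fold-fitted standardization option
  exists to avoid leakage when enabled.
* **Fold structure.** "Leave one out" holds out one subject *from each
  group* per fold (folds = min(n₁, n₂)), pairing subjects by their
  order within group; a seed-shuffled pairing and a one-subject-per-fold
  variant are options. Metrics come from the pooled held-out
  predictions; AUC from pooled decision values by the rank
  (Mann–Whitney) formulation with ties at 0.5.
* **Exact Gram-factor training.** The linear-SVM dual depends on the
  data only through the Gram matrix, so each fold is fit on the
  Cholesky factor of the training Gram (an n×n problem rather than
  n×V), and held-out decision values follow from the dual
  coefficients. This reproduces the raw-feature solution to libsvm's
  working tolerance and is what makes 200-fold permutation testing of
  the full cross-validation loop affordable; equality with a direct
  raw-feature fit is tested.
* **Permutation test**: labels permuted over the whole sample, the
  *entire* cross-validation re-run per permutation, add-one p.
* **Weight maps**: full-sample SVM weights back-projected to the grid
  (positive = patient-ward); the top 20% of in-mask voxels by |weight|
  (ties: smaller linear index) form the discriminative mask. A
  user-supplied integer label image yields per-region percentages of
  the top-mask |weight| mass (no atlas ships with the package).

# Numerical and degenerate-input conventions

* Zero-variance in-mask voxels make correlations undefined: hard error
  listing the offending voxel indices.
* A perfect voxel-wise fit (zero residual) yields t = 0 when the group
  coefficient is also zero, ±∞ otherwise.
* B = 0 permutations is an error ("inference impossible"); an empty
  cluster set yields an empty report, not an error.
* Rank-deficient designs error out naming the collinear columns.
* Voxel indices are 0-based internally wherever they meet an affine;
  all reported coordinates are world mm.
* Sex is coded F = 0 / M = 1 as a covariate (the coding convention is
  documented rather than assumed).

# Validation-suite problem sizes

The package's calibration and recovery suites run at sizes chosen for
a single desk CPU, fixed before the suites were first executed:

* **Null calibration of cluster FDR**: 50 exchangeable cohorts,
  10 + 10 subjects, 16³ grid, 70 volumes, 200 permutations; the
  family-wise rate of any significant cluster must sit inside the
  exact binomial 95% band around q = 0.05. Calibration does not depend
  on series length, so the short series keeps the suite fast.
* **Planted-effect recovery**: 15 + 15 subjects, 12³ grid, 240 volumes
  (the full-length design the generator defaults to), 20 replicates
  for cluster recovery and 10 for MVPA (accuracy ≥ 85%, permutation
  p ≤ 0.05 at B = 200).
* **MVPA null calibration**: 60 signal-free cohorts, 10 + 10 subjects,
  10³ grid; p-values of the cross-validated AUC — a near-continuous
  statistic, chosen because accuracy's coarse grid (multiples of 5%
  at this n) makes its Monte-Carlo p-values heavily tied — compared to
  uniformity by Kolmogorov distance at the n = 60 bound (a larger
  replicate count tightens the bound, making this the stricter form of
  the check).
* **End-to-end smoke**: 12 subjects, 16³ × 60 volumes through the full
  `run_pipeline()` with 200 permutations.

# Known limitations

* The generator omits scanner artifacts, slice-timing offsets, head
  motion, physiological noise structure, anatomical geometry, and
  spatial autocorrelation of the noise; passing recovery tests
  demonstrates correctness of the analysis chain on its declared model,
  not performance on real scanner data.
* The planted effect is categorical and strong by design (see above);
  real case-control hub differences are graded and smaller.
* Cluster inference assumes exchangeability of subjects under the null
  given the covariate-attached permutation scheme; covariate-dependent
  variance is not modeled.
* No nonlinear kernels, no nested hyperparameter search, no
  multi-class problems, no atlas, no DICOM/BIDS ingestion.
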