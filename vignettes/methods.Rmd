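---
title: "Methods: multimodal sex-difference analysis on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal sex-difference analysis on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What this package computes

`sexdiffmri` implements a complete multimodal group-difference analysis
for structural and resting-state functional MRI, of the kind used to ask
whether two groups (here: males and females of a young-adult cohort)
differ in brain structure, in brain function, whether those differences
coincide spatially, and whether the joint multivoxel pattern can predict
group membership. Three imaging measures are computed per subject:

* **GMV** — voxel-wise gray-matter volume (taken as input; the package
  starts from preprocessed, spatially normalized maps);
* **ReHo** — regional homogeneity, the voxel-wise Kendall coefficient of
  concordance $W$ between a voxel's BOLD time series and its 26
  neighbors, measuring local temporal synchrony;
* **FC** — functional connectivity, the Fisher-z-transformed Pearson
  correlation between the mean time series of every pair of atlas
  regions.

Since no public data accompany the emulated study, the package carries a
first-class synthetic-cohort generator with known ground truth; every
downstream stage is tested against planted effects.

## The synthetic world

`cohort_spec()` fixes the stated world. Its defaults are the emulated
cohort: 135 males and 155 females, ages uniform on 18–29 years,
education uniform on the group mean ± 2 SD (15.13 ± 2.33 male,
15.86 ± 2.61 female — uniform because only ranges and moments are
stated), 180 BOLD volumes at TR = 2 s. The grid is a 24³ box
(3 mm voxels) with an ellipsoidal "brain" of ≈ 5,200 voxels and a
12-region parcellation: small enough for seconds-scale tests, large
enough to support genuine 26-neighborhoods. The parcellation is a
deterministic chop of the mask into near-equal slabs — it is a
partition, not anatomy.

A published demographic detail is deliberately not matched: the
emulated study prints an age comparison (T = 2.5, P = 0.01) that is not
reproducible from its own printed means and SDs at the printed group
sizes (the standard pooled computation gives |t| ≈ 3.9). The generator
draws from the printed ranges and makes no attempt to hit those
statistics.

**GMV maps.** Each in-mask voxel is
`baseline + 1(female)·d·σ·1(cluster) + slopes·(age, education) + N(0, σ)`,
clipped at zero, with σ = 0.1 and baseline 0.6 (a plausible tissue
fraction scale). Effect clusters are spheres with Cohen-type effect
size `d`; the default world plants one female-greater and one
male-greater cluster at d = ±1.5, the size of effect the emulated
analyses detect comfortably at n ≈ 40/group.

**BOLD runs.** Voxel series are
`w·L[region] + c·B[block] + N(0, 1)`, where `L` are per-region latent
signals drawn with a gender-specific target correlation matrix
(`base 0.1` everywhere, planted female-minus-male deltas on chosen
edges; Cholesky-factorized after a nearest-positive-definite repair if
the deltas break PD — this gives exact control of the FC ground truth),
`B` are signals shared within 3×3×3 spatial blocks, `w = 0.4`, and
`c = 0.3` by default. Local coherence drives ReHo: inside a planted
ReHo cluster the female group's `c` is raised by `0.1·d`.

*Why `0.1·d`:* for two neighboring voxels in one block and one region,
the shared-variance fraction is $(w^2+c^2)/(w^2+c^2+1)$. Moving `c`
from 0.30 to 0.45 (d = 1.5) moves that fraction from ≈ 0.20 to ≈ 0.27,
a ΔW of ≈ 0.05–0.07 against a between-subject sampling SD of W of
≈ 0.02–0.04 at 80–180 time points — a standardized difference of the
order of `d`. The mapping was fixed from this argument, not adjusted
against test outcomes.

Six pseudo-motion parameters (random walks, innovation SD 0.02) and a
linear + sinusoidal drift pair accompany every run so nuisance
regression is exercisable. What the generator does **not** emulate:
anatomy, scanner artifacts, motion-induced image changes,
autocorrelated (1/f) BOLD noise, distance-dependent connectivity. A
green test therefore establishes algorithmic correctness and
statistical calibration under Gaussian noise — not robustness to real
scanner physics.

## Feature extraction

The preprocessing order follows the emulated protocol: band-pass
filter → nuisance regression → (ReHo | region means → FC).

* **Band-pass (0.01–0.08 Hz)** is zero-phase rectangular masking in the
  frequency domain, as in the resting-state toolbox lineage; the DC bin
  is always removed. Band edges must satisfy
  `0 ≤ low < high ≤ 1/(2·TR)`.
* **Nuisance regression** is per-voxel OLS against an intercept plus
  caller-supplied regressors; residuals are exactly orthogonal to every
  column. The pipeline regresses drift, the six motion parameters and
  the global in-mask mean. The emulated protocol also regresses WM and
  ventricle means; the synthetic world has no non-GM compartments, so
  these regressors do not exist here. (Using atlas-region means as
  stand-ins is wrong: a regressor that *is* a region's mean series
  nulls that region's FC signal exactly.)
* **ReHo** implements
  $W = 12\sum_t (R_t-\bar R)^2 / (K^2 (n^3-n))$ with average-rank ties
  and no tie-correction term (the original formulation; continuous
  synthetic data make ties measure-zero). At mask edges `K` shrinks to
  the available in-mask neighbors so the feature count equals the mask
  size; a voxel with no in-mask neighbor is undefined, dropped from the
  output mask and flagged. The map is then standardized by its in-mask
  mean and smoothed — KCC → standardize → smooth, in that order.
* **Smoothing** uses a separable Gaussian with
  σ = FWHM/(2√(2 ln 2)) per axis and *mask renormalization*: kernel
  weight falling outside the mask is discarded and the rest rescaled,
  so constants are preserved and nothing bleeds across the mask edge.
  The emulated protocol does not state its boundary handling; this is a
  documented divergence risk.
* **FC** clamps r to ±(1 − 10⁻⁷) before `atanh` so z stays finite
  (the emulated protocol is silent on degenerate correlations).

## Group statistics

Voxel-wise and edge-wise comparisons share one GLM:
`value ~ intercept + gender + covariates`, with t the gender
coefficient's statistic and the sign convention female-minus-male.
Covariates (age, education) are partialled inside the model, not
pre-residualized. Exactly-fitted (constant) columns are flagged and set
to t = 0 with a warning.

Family-wise error control offers **Bonferroni** and **max-T
permutation** (whole-label shuffles, two-sided, threshold at the
1 − α quantile of the permuted maximum |t|). The emulated study used
SPM's random-field theory for its voxel-level FWE; RFT is deliberately
not implemented — it buys nothing on synthetic data and adds a large
untestable surface. Max-T is the default: assumption-light and itself
testable (the suite verifies its family-wise error on 100 null
replicates). Edge families use Bonferroni at `α/E`,
`E = R(R−1)/2` — for 116 regions, 0.05/6670 ≈ 7.5×10⁻⁶. Per-region
**weighted degree** sums positive and negative t separately over each
region's significant edges.

**Convergence** between two modalities' difference maps is quantified
by (1) the overlap of corrected significance masks, as counts and as
percentages of each mask; (2) the same with one map relaxed to an
uncorrected trend threshold (two-sided p < 0.001); and (3) the Pearson
correlation of the unthresholded t-maps over the analysis mask. Trend
masks are direction-agnostic, but the report breaks out sign agreement
separately. Empty corrected masks yield `NA` percentages with counts
still reported.

## Classification protocol

Features are prepared per modality: covariate effects removed from
every feature by linear regression over **all** subjects — faithful to
the emulated protocol, and a documented leakage choice; passing
training rows via `fit_rows` gives the strict-CV variant — then (for
the combined analysis) each subject's feature vector is z-normalized
across that modality's features using the population-SD convention
(divide by n; the protocol does not state a convention, so one is fixed
and pinned by tests) and the modalities concatenated.

Cross-validation uses stratified folds with a remainder fold: each of
the first k−1 folds holds ⌊n_g/k⌋ subjects of group g, the last fold
everything else (135/155 at k = 10 → nine folds of 13 + 15 and a last
fold of 18 + 20). Per fold, a linear SVM is trained on all features,
features are ranked by |weight| (ties broken by ascending index, for
determinism), and the classifier is retrained on each top-k set of the
grid `(step, 2·step, …, total)`. The overall accuracy per grid point is
the unweighted mean of fold accuracies (the protocol's stated rule,
although folds differ in size; a pooled-count accuracy is also
reported). Sensitivity is the pooled fraction of males classified male,
specificity the pooled fraction of females classified female. ROC/AUC
pool decision values across test folds at the best grid point (males
positive; ties count one half).

The **SVM** is written in-package (no SVM implementation exists in the
supported R stack): LIBLINEAR-style dual coordinate descent for the
hinge-loss, L2-regularized linear SVM, with the bias handled as an
appended constant feature and a fixed iteration order, so fits are
bit-reproducible. C defaults to 1 (the protocol names no value;
configurable). One consequence of the regularized-bias convention
(shared with LIBLINEAR/LinearSVC): if the two class clouds sit far from
the origin, the large intercept is penalized and the solution tilts.
Residualized features are mean-centered, so the pipeline is unaffected,
but users feeding raw features should center them.

**Permutation testing** shuffles the training labels within every
fold's training set, reruns training + ranking + top-k evaluation at
the *same grid point as the actual analysis* (re-optimizing per
permutation is a defensible alternative reading of the protocol; the
fixed-grid-point choice is conservative in compute and reported as
such), and repeats `n_perm` times. The p-value is the fraction of null
accuracies ≥ the actual one, floored at 1/n_perm, with the grid size
reported as a Bonferroni factor.

## Numerical and design choices

* All randomness flows from one master seed through named substreams
  (table / gmv / bold / folds / fwe / perm), so stages are individually
  and jointly reproducible.
* NIfTI-1 I/O is implemented in-package (348-byte header, `.nii` and
  `.nii.gz`, little/big-endian read, scl slope/intercept honoured) —
  no R NIfTI reader is available in the supported dependency set.
* Voxel indices are 1-based in R, and reported peak coordinates are
  voxel indices on the synthetic grid; there is no MNI mapping because
  synthetic space has no anatomy.
* Ranking ties in the GLM/KCC use average ranks; |weight| ranking ties
  use ascending feature index.
* The feature grid always ends exactly at the total feature count, with
  the preceding points at multiples of the step below it.

## What the tests establish (and what they do not)

The suite verifies: exact protocol arithmetic (edge counts, Bonferroni
thresholds, grid sizes, fold compositions, the 141,752-feature
concatenation, the 1/2000 permutation floor); equivalence of ReHo with
a brute-force rank oracle to 10⁻¹²; reduction of the GLM to the
closed-form pooled t without covariates to 10⁻¹⁰; type-I calibration
of the voxel tests and family-wise control of max-T under the null
(200 and 100 seeded replicates); recovery of planted GMV, ReHo and FC
effects (d = 1.5 clusters, Δr = 0.4 edges) in ≥ 90% of 20 replicates;
classifier sanity (≥ 95% on separable features, a 0.50-centred
permutation null, combined ≥ best single modality when modalities carry
independent signal); and exact agreement of the AUC with the O(n²)
pairwise oracle. Simulation-based checks run on reduced grids (10–16
voxels per side, 48–80 volumes) to keep the suite inside a CI budget;
replicate counts, effect sizes and thresholds are not reduced.

The study-specific empirical numbers of the emulated analysis
(accuracies of 94.3/90.73/83.89/96.6%, the 33 significant connections,
the 20-voxel overlap, r = 0.1033, and all peak anatomy) depend on MRI
data that are available only on request and are out of scope: this
package reproduces the *machinery* and its calibration, not those
numbers.
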