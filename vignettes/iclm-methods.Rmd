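---
title: "Independent component-based lesion mapping: model, parameters and validation"
author: "iclm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent component-based lesion mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focal brain lesions produce behavioral deficits that depend less on the
damaged tissue itself than on the distributed network the tissue belongs
to. Two classical tools probe this link. Voxel-based lesion-symptom
mapping (VLSM) compares behavior between patients lesioned versus spared
at each voxel; it needs many patients to overlap at the same voxels, and
fails when lesion locations are heterogeneous. Lesion network mapping
(LNM) seeds each patient's lesion in a *normative connectome* — resting-
state fMRI from healthy subjects — to find the remote network that the
lesion disconnects, then overlays thresholded per-patient maps; with
dispersed lesions the strict overlay (e.g. voxels shared by 90% of
patients) is often empty.

This package implements independent component-based lesion mapping
(ICLM), which replaces the overlay with a matrix decomposition. Averaged
lesion-seeded connectivity vectors are stacked into one patients-by-
voxels matrix and decomposed with spatial ICA into a small set of
independent networks; the symptom-related network is identified against
reference maps, and per-patient damage to it is correlated with behavior.

## The model

Each patient's binary lesion mask is used as a seed region in every
normative scan: the Fisher-Z transformed Pearson correlation between the
mean seed time course and every other in-brain voxel gives one
connectivity vector per scan, averaged within and then across healthy
subjects. Stacking the per-patient averages (lesion voxels filled with
exact zeros, rows standardized) gives the union FC matrix
`X (M patients x V voxels)`, modelled as a noiseless linear mixture

    X = A S,        S_hat = W X,

with `A` a full-rank mixing matrix and `S` spatially independent source
maps. Because the model only holds in a signal subspace, `X` is first
reduced by PCA; the subspace order is the knee point of the cumulative
explained-variance curve. Infomax ICA with the logistic nonlinearity and
the natural-gradient update `dW = lrate (I + (1 - 2 g(Y)) Y'/B) W`
estimates `W`; since the optimization is stochastic, it is restarted
`nRuns` times and the restart minimizing the mean pairwise Amari
inter-symbol interference (cross-ISI) against the other converged
restarts is kept. Sources are z-scored over brain voxels, sign-oriented
to positive skewness, and thresholded at |Z| > 1 into network maps.

The identified component (best mean rank of Dice and spatial correlation
against the reference networks) yields a per-patient *network damage
score*: the maximum z-value inside the intersection of the thresholded
map and the patient's lesion. Lesion size is regressed out of the scores
before Pearson correlation with the behavior measures. For binary
reference networks, where a maximum z is not defined, the intersection
voxel count z-scored across the cohort is used instead.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band` | 0.01–0.08 Hz | zero-phase ideal band-pass on normative scans |
| `globalSignal` | TRUE | regress the brain-mean series (see below) |
| `zscoreScope` | "row" | FC-matrix standardization scope ("global" available) |
| `order` | knee point | PCA subspace order override |
| `nRuns` | 30 | ICA restarts entering cross-ISI selection |
| `icThreshold` | 1.0 | z threshold of network maps (0.5 / 1.5 alternates) |
| `overlayFractions` | 0.7, 0.8, 0.9 | LNM overlay commonality thresholds |
| `vlsmFracs` | 0.25, 0.75 | VLSM voxel eligibility bounds |
| `alpha` | 0.05 | VLSM FDR level |
| `lnmAlphaCorrected` | 1e-6 | LNM Bonferroni-corrected significance |

Infomax internals: initial learning rate `0.01 / ln(q e)`, mini-batches
of `min(V, 256)` voxels, at most 2048 full passes, convergence when the
per-pass Frobenius weight change drops below `1e-6`. The learning rate
anneals by 0.9 whenever the update direction turns by more than 60
degrees — near a fixed point the mini-batch gradient direction is
isotropic noise, so annealing cascades and the weight change falls
through the tolerance; on divergence the rate is halved and the pass
restarted from the last good weights.

## Numerical choices

* Correlations are clamped to `±(1 - 1e-7)` before `arctanh`, bounding
  Fisher-Z values at about 8.41 for duplicated series.
* The knee-point chord is anchored at the zero-component origin (0
  components explain 0 variance); ties break to the smallest order, and
  a flat curve returns order 1 with a warning. The selected order is
  floored at 2, the smallest subspace ICA can rotate.
* Row standardization uses the sample (n-1) standard deviation over the
  non-lesion entries only, with lesion zeros restored afterwards, so the
  "missing data are zeros" convention survives standardization. The same
  n-1 convention applies to every cohort z-score.
* Sign indeterminacy is resolved by positive skewness: a super-Gaussian
  spatial source carries its network in the heavy tail, so the network
  side becomes positive.
* The cross-ISI matrix symmetrizes the two directions
  `ISI(W_i W_j^-1)` and `ISI(W_j W_i^-1)` by averaging.
* Grids must agree within 1e-4 mm on affine entries; nothing is silently
  resampled (an explicit nearest-neighbour resampler is provided for
  reference maps so binary masks stay binary). Non-finite voxels in any
  input are an error, never imputed.
* An empty lesion/network intersection scores 0 with a warning; the
  patient is kept, because silently dropping patients would change the
  correlation sample size invisibly.
* Comparing two correlations uses the independent-samples Fisher r-to-z
  test. The package's correlations share one behavior vector, so a
  dependent-correlations test (e.g. Steiger's) would be slightly more
  appropriate; the independent version is reported and this caveat
  documented rather than hidden.

## What the synthetic generator emulates

No patient MRI or normative cohort ships with the package, so every
stage is validated on synthetic cohorts with the statistical structure
the method assumes (`simulateCohort()`, defaults in
`defaultCohortConfig()`):

* **Networks**: K = 4 spatial sources on an 18^3 grid (4 mm voxels),
  each a *pair* of Gaussian blobs (sd 2 voxels, truncated at 2 sd)
  sharing one unit-variance source time course; blob centres keep a
  minimum mutual distance and placements are redrawn until all pairwise
  network map correlations are below 0.2. Networks are deliberately
  multi-regional: a lesion can destroy one node while the remote node
  still carries the network's connectivity signature — the premise that
  makes lesion network mapping work at all. With single-blob networks a
  heavily lesioned network would self-erase from the FC matrix.
* **Normative scans**: 20 subjects, one 150-timepoint session each (TR
  2 s). A voxel's series is the map-weighted sum of that subject's fresh
  source realizations plus white Gaussian noise; SNR (default 1) is
  sd(signal)/sd(noise) at a network's peak voxel.
* **Lesions**: 24 compact blobs of exactly 30–150 voxels, centred with
  Gaussian jitter (sd 2.5 voxels) around a blob of a network drawn from
  the hit profile, retried until the lesion touches that network's
  support. The default profile weights the target network 3:1 over each
  other network: the emulated cohort is recruited for the target deficit
  (as an aphasia cohort is), so the symptom network is damaged
  throughout the cohort and in any random subgroup, while other networks
  stay represented enough that the decomposition faces a genuine
  multi-network problem. Pairwise lesion overlap stays low (mean Dice
  about 0.03–0.05) — the heterogeneity regime where overlay methods
  fail.
* **Behavior**: the AQ-like severity score is `90 - 60 * damage +
  N(0, 5)` clipped to 0–100, where damage is the maximum target-network
  map value inside the lesion; subtest scores use slopes scaled to their
  WAB ranges. The generating slopes are stored for recovery tests.

All sub-seeds derive deterministically from one master seed; the same
seed reproduces a cohort and a full pipeline run bit-identically.

**Global-signal regression and the synthetic default.** The pipeline's
`defaultRunConfig()` keeps global-signal regression on, matching the
standard normative-connectome preprocessing. The validation harnesses
and the acceptance script run synthetic studies with
`globalSignal = FALSE`, for a structural reason worth recording: GSR
forces the brain-wide average correlation toward zero, so the K planted
network FC patterns collapse onto a (K-1)-dimensional simplex — one
network becomes expressible only as minus-the-sum of the others and
cannot surface as a positive component. With K = 4 that deletes a
quarter of the planted structure (empirically the patient-dominant
network); in real brains, with many more than four networks and genuine
global nuisance signal, the constraint is negligible and GSR earns its
keep. The generator plants no global confound, so on synthetic data GSR
removes only signal.

**What passing tests do not show.** The generator omits hemodynamics,
head motion, physiological noise, spatial autocorrelation of noise,
multi-site effects, and white-matter disconnection. Passing recovery
tests therefore demonstrate the correctness of the pipeline's
computations and the identifiability logic under the method's own
assumptions — not that those assumptions hold in clinical data.

## Validation harnesses and problem sizes

The reproducibility harness (`splitHalf()`) drops one random patient
when the cohort is odd, splits the rest into equal halves, runs the core
pipeline per half, and records the Dice coefficient between the two
identified positive masks; `subgroupRuns()` compares labelled subgroup
maps against the full-cohort map; `robustnessScan()` reruns the pipeline
over normative-subset sizes and rethresholds the identified component at
looser/stricter cutoffs (0.5 / 1.5).

The test suite and `scripts/acceptance.R` exercise the default cohort
scale (18^3 grid, 4 networks, 20 normative subjects, 24 patients) over
ten master seeds with 8 ICA restarts per decomposition, and a smaller
fixture (14^3 grid, 2 networks, 4 subjects, 8 patients) for unit-level
checks — sizes chosen so a complete run stays within minutes on a single
CPU while leaving the decomposition a non-trivial four-network problem.
Typical results at this scale: the identified component correlates
about 0.97 with the planted network, split-half mean Dice is about
0.83–0.94, the 90% LNM overlay is empty, and the residualized damage
score correlates about -0.9 with the AQ-like measure (the generating
slope is strong and the noise modest; real-data effect sizes are far
smaller).

## Known limitations

* Non-extended Infomax only; sub-Gaussian sources would need extended
  Infomax or FastICA, deliberately out of scope.
* The cross-ISI aggregation (mean pairwise Amari index against converged
  restarts) is one defensible reading of "most consistent run"; run-pair
  aggregation variants exist.
* VLSM uses parametric two-sample t-tests with BH-FDR; permutation
  inference and cluster-extent corrections are not implemented.
* Inputs are assumed co-registered; the package performs no spatial
  normalization, and the nearest-neighbour resampler is for reference
  maps, not for data.
* White-matter tract damage, which can produce network dysfunction
  without cortical lesion overlap, is outside the model.
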