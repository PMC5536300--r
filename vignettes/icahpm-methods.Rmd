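---
title: "Methods: single-subject ICA with hierarchical partner matching and Granger causality"
author: "icahpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-subject ICA with hierarchical partner matching and Granger causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icahpm)
```

# Overview

`icahpm` implements a resting-state fMRI functional-connectivity analysis
for two-group designs (a patient-like group, e.g. persons who stutter, and
matched controls): per-subject spatial independent component analysis (ICA)
over a range of model orders, two-stage Hierarchical Partner Matching (HPM)
to find components that are reproducible across participants and across
model orders, voxelwise second-level inference with Monte-Carlo
cluster-extent correction, direct and mediated Granger causality between
the reproducible components, and SVM / regularized-LDA classification of
the two groups from the resulting connectivity and causality features.

Because public BOLD data with known ground truth do not exist, the package
ships a synthetic cohort generator that plants exactly the statistical
structure the analysis is designed to recover — spatially smooth sources,
directed lagged dependencies between their time courses, group differences
in amplitude and in lagged coefficients, a severity covariate, and
motion-corrupted volumes. Every pipeline stage is validated against this
generator or against closed-form oracles.

# The processing model, stage by stage

## Preprocessing

The first six volumes of each run are discarded (signal stabilization
after onset transients; a 146-volume acquisition retains 140 volumes).
Artifact volumes are detected from two statistics: the first-order
derivative of the motion parameters between successive volumes
(translations only by default; rotations can be folded in as arc
displacement at a 65-mm head radius) and the z-scored global mean signal.
The default thresholds are 0.5 mm and |z| > 3; artifact-repair practice
varies, so both are arguments, and the generator's planted-artifact recall
(≥ 0.9 over seeds) pins the behaviour. Flagged volumes are replaced by
voxelwise linear interpolation between the nearest clean volumes (runs at
either end copy the single nearest clean volume), so repairing twice is the
identity. Finally each volume is smoothed with an isotropic 8-mm-FWHM
Gaussian. Smoothing is separable per axis with the kernel truncated at
3 sd and renormalized row-wise; this edge convention preserves constant
images exactly and the per-volume global mean to within 0.1%, at the cost
of slight mass redistribution within one kernel radius of the grid
boundary. Slice-timing correction, rigid-body realignment and template
normalization are out of scope: the synthetic data are generated in a
common grid.

## PCA reduction and spatial ICA

For each subject the T x M time-by-voxel matrix (mask voxels as columns,
each voxel's series mean-centred) is reduced to its top-N whitened
principal components, N being the ICA model order. Whitening is exact:
the N x M reduced matrix has identity row covariance over voxels, and the
discarded variance equals the sum of the dropped eigenvalues of the T x T
voxel-averaged covariance.

Spatial ICA maximizes the non-Gaussianity of the rows with the symmetric
fixed-point iteration under the log-cosh contrast; the unmixing matrix is
orthonormal in whitened space. Three numerical choices matter:

* **Tolerance and stopping.** The default tolerance on the unmixing rows
  is 1e-4 — the convention of the widely used fixed-point ICA
  implementations. A stricter 1e-5 leaves noisy decompositions orbiting a
  limit cycle just above threshold. Conversely, the iteration can dip
  under tolerance for a single step while traversing a saddle, so the
  search only stops after **two consecutive** fully-converged iterations
  (cap 500, both configurable).
* **Partial convergence.** At model orders beyond the true source
  dimension, the trailing whitened directions are near-Gaussian noise with
  no stable fixed point; their rotation perturbs every row slightly. The
  estimator therefore keeps the most stable iterate seen and reports
  per-component convergence flags; if no component ever stabilizes, it
  restarts from fresh seeded initializations before raising an error.
* **Sign and order conventions.** An IC's map and time course can be
  jointly negated without changing the model, so each map is flipped to
  nonnegative skewness, z-scored over mask voxels (mean 0, sd 1), and
  components are ordered by decreasing map kurtosis. These conventions
  make matching and one-sample t tests well defined.

The full-scale model-order schedule is 20 to 130 in steps of 10 (12 sets
of ICs per subject). On the desk-scale synthetic grid 130 components are
degenerate, so analyses in this package's tests use 10 to 40 in steps of
10; the schedule is a config parameter and the full-scale default is kept
in `validateConfig()`.

## Hierarchical partner matching

Spatial similarity between two z-maps is the Tanimoto coefficient
$T = \langle a,b\rangle / (\langle a,a\rangle + \langle b,b\rangle -
\langle a,b\rangle)$ computed after clipping negative z to zero
(continuous mode, the default — it avoids an arbitrary binarization
threshold); a binary intersection-over-union mode at z ≥ 2 is retained for
sensitivity analysis. Two components of different subjects are *partners*
when each is the other's most-similar component (mutual best match, ties
to the lowest component index).

Stage 1 matches all subject pairs within one model order, forms the graph
of partner edges, and keeps connected components containing at least half
of the subjects. The pairwise definition only fixes matching for two
subjects; connected components are the minimal transitive extension, and
the membership floor is exposed. If transitivity pulls two components of
one subject into a cluster, the one with the higher mean similarity to the
other members is kept, so each subject enters later t tests once. A
cluster's map is the voxelwise one-sample t over its member maps (voxels
with zero variance and zero mean give t = 0; zero variance with a nonzero
mean returns a configurable cap with a degeneracy flag).

Stage 2 applies the same bidirectional matching to the stage-1 cluster
maps across model orders and keeps order-level components present in at
least half the orders whose Cronbach's alpha is at least 0.7 (the
conventional reliability bar; items are the member cluster maps, voxels
the observations). Each retained component becomes a
`ReproducibleCluster`: the per-subject representative z-map is the mean of
that subject's member ICs pooled across orders, and the final t map is
recomputed from the representatives.

## Voxelwise group inference

Per cluster, the subject representative maps enter an ordinary
least-squares model with group, age and sex columns (optionally an
age-by-group interaction); the group contrast t equals the pooled
two-sample t when no covariates are present. Significance is assessed at
an uncorrected two-sided voxel p of 0.01 combined with a cluster-extent
threshold determined by Monte-Carlo simulation at a familywise error rate
of 0.05: smooth Gaussian null fields are synthesized on the mask (white
noise convolved to the smoothness estimated from the residual maps' lag-1
spatial autocorrelation, Gaussian ACF fit per axis, geometric mean),
z-scored, thresholded two-sided, and the threshold is the smallest extent
whose exceedance probability under the null maxima of 26-connected
cluster size is at most the FWER (judged by its one-sided 95% upper
confidence bound, so Monte-Carlo error cannot tip the choice into an
anticonservative threshold). Suprathreshold
clustering of the real t maps uses the same 26-connectivity, positive and
negative excursions separately. Simulating Gaussian rather than Student
null fields makes the procedure very slightly anticonservative at small
degrees of freedom; calibration on 200 null cohorts stays inside the 95%
binomial band around the nominal rate, which is the property the tests
assert.

Severity association is the Pearson correlation between the per-subject
mean representative z over a cluster's surviving voxels and the
standardized severity score, in the patient group.

## Granger causality

Cluster time courses per subject are the standardized time courses of the
subject's member ICs (first principal component, sign-aligned to the mean,
when a subject contributed several members across orders). The Granger
causality index from x to y at lag order p is the log ratio of residual
sums of squares between the model of y on p of its own lags and the model
adding p lags of x — nonnegative by nesting and invariant to rescaling
either series. The mediated index through m is the conditioning drop
max(0, GCI(x→y) − GCI(x→y | m)), the conditional index adding lags of m to
both models; the path-product alternative min(GCI(x→m), GCI(m→y)) is
available via an argument. The lag order is selected once per cohort by
BIC over a joint VAR of the cluster time courses (comparability of indices
across edges), capped at 3 by default.

Two facts about mediated indices at realistic series lengths deserve
emphasis. First, a lag-1 mediated index only exists when the driver is
autocorrelated — a white-noise source carries no information about its own
past, so a two-step chain is invisible at lag 1. Second, with 140 volumes
per subject the chain-mediated index is close to zero and its group
difference is not reliably detectable; the mediated-index analytics are
therefore validated on long simulated series (T = 5000), while at cohort
scale the detectable signatures of a weakened chain are its two legs.

Group comparison per edge reports the per-group median and interquartile
range, a Wilcoxon signed-rank p against zero per group, and a two-sided
Wilcoxon rank-sum comparison between groups — z from the normal
approximation with tie correction, with the exact enumeration p for small
untied samples; positive z means the patient-like group is larger. A
two-sample Welch t is available via an argument; the rank-sum test is the
default.

## Classification

Features are per-subject scalars: the mean representative z over each
significant cluster's surviving voxels, and the per-subject GCI of each
significant edge. Selection of the significant clusters and edges happens
once on the full sample — as the analysis this package operationalizes
did — so the cross-validated accuracies are optimistic with respect to
that selection step; within each CV fold, however, imputation (training
median) and standardization use training subjects only, and a constructed
leakage test asserts the difference.

The SVM uses the Gaussian kernel
$K(u, v) = \exp(-\lVert u-v\rVert^2 / (2 w^2))$ with width w = 0.5 on
standardized features and soft-margin cost 1, under leave-one-out or
stratified seeded 5-fold cross-validation. Note that w = 0.5 is a *narrow*
kernel on standardized features — distant points are nearly orthogonal and
the classifier behaves like a smoothed nearest-neighbour rule. Two
consequences are documented rather than hidden: separable classes still
classify perfectly, but the leave-one-out permutation null sits slightly
*below* 0.5 (with the kernel nearly degenerate the decision often falls to
the bias term, and the held-out subject's class is always the training
minority). The width-as-gamma reading is available via an argument.

The regularized discriminant (maximum-uncertainty LDA) replaces
eigenvalues of the pooled within-class covariance that fall below the
eigenvalue mean by that mean, making the inverse well defined even with
more features than subjects; subjects are assigned to the nearest class
mean along the discriminant with the midpoint threshold, sensitivity is
reported on the patient-like class, and per-feature contributions are the
absolute hyperplane coefficients scaled by the largest. Repeated
leave-one-out evaluation of a named feature subset (1000 trials by
default) jitters imputed entries per trial and reports the mean accuracy
and its across-trial sd; with complete data the trials coincide and the sd
is 0.

# The synthetic cohort generator

`cohortSpec()` fixes the study conditions; `generateCohort()` realizes
them. Each subject's data are
$X(v, t) = \sum_k a_k\, \mathrm{map}_k(v)\, s_k(t) + \varepsilon(v, t)$
with i.i.d. Gaussian voxel noise. Defaults, with rationale:

* **Acquisition**: 146 volumes at TR 2.2 s; six are discarded by
  preprocessing. Grid 16 x 16 x 12 voxels at 3.75 x 3.75 x 3.5 mm — a
  desk-scale stand-in for a 64 x 64 whole-brain acquisition over a 24-cm
  field of view with 3.5-mm slices, preserving the smoothness-to-voxel
  ratios at toy scale.
* **Design**: 20 patients + 20 controls by default (the emulated
  full-scale design is 44 + 50); ages uniform on 8–49 years; sexes
  assigned proportionally to the emulated design's group counts.
* **Sources**: K = 4 unit-peak Gaussian blobs of 12-mm FWHM, placed
  deterministically by farthest-point selection inside the interior
  quarter-box of the grid (interior placement keeps blob support away from
  the grid boundary; determinism keeps the canonical geometry part of the
  study design, identical across seeds — only noise realizations change
  with the seed). Pairwise canonical correlations are below 0.3 by
  construction. Each subject's copies are translated by a random offset of
  at most 1.5 mm (uniform direction and magnitude), giving
  subject-to-canonical correlations around 0.97
  ($\exp(-d^2/4\sigma^2)$ for a shifted Gaussian).
* **Dynamics**: source time courses follow a per-group stationary VAR(1)
  with self-coefficients 0.3 and planted directed edges 1→2, 3→4 and 4→2
  at 0.35 in the control-like group (3→4→2 is the planted mediated chain).
  Stationarity is asserted on the companion-matrix spectral radius at
  construction.
* **Group effects**: the patient-like group halves every planted directed
  coefficient (both chain legs included) and carries amplitude ratios 0.7
  on sources 1 and 3 and 1.3 on source 2. Source 2 sits at a lower
  baseline strength (0.6) than the others: spatial z-scoring makes the
  blob z-value a saturating function of amplitude, so an amplitude
  *increase* on a strong source is nearly invisible while the same ratio
  on a weaker source is detectable. Even so, detection of the full
  extent-corrected positive cluster has only partial power (roughly
  two-thirds of cohorts) at n = 20 + 20 — the saturation asymmetry is a
  property of z-scored spatial maps, not a bug — and the package's tests
  assert a positive suprathreshold excursion over the planted support
  rather than guaranteed cluster survival. The amplitude-reduced sources
  are detected with near-certain power.
* **Noise**: voxel noise sd 2.0 against unit-peak sources, i.e. a
  per-timepoint single-network SNR of about 0.5, which is the regime of
  real BOLD data; with much cleaner data the z-maps saturate and amplitude
  effects vanish by construction. Per-subject amplitudes carry a 10%
  log-normal jitter — real networks differ in strength between subjects,
  and the severity covariate needs between-subject amplitude variability
  to correlate with.
* **Severity**: standardized scores for the patient group with population
  correlation −0.30 to the severity source's (source 1) amplitude,
  constructed as $r\,z(a) + \sqrt{1-r^2}\,\epsilon$ and standardized; the
  instrument's raw scale is not reproduced.
* **Artifacts**: each volume is independently corrupted with probability
  0.03: a 2-mm translation spike in the motion trace plus a global-signal
  offset. The clean motion baseline is a slow random walk (0.02-mm steps)
  far below the detection threshold.

What the generator does **not** emulate: physiological (cardiac or
respiratory) noise structure, scanner drift, slice-timing offsets, EPI
distortion, anatomical variability beyond rigid source jitter, or
non-Gaussian noise. Passing tests therefore show that the implementation
recovers the structure it models, under realistic SNR and sample sizes —
not that it is robust to every artifact of real acquisitions.

# Problem sizes in the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on the
default 16 x 16 x 12 cohort (40 subjects, orders 10–40), validate the GCI
analytics on series of length 2000–5000, calibrate the familywise error
on 200 null cohorts of 20 maps on a 12 x 12 x 8 grid (extent threshold
from 2000 Monte-Carlo iterations), and estimate the severity recovery
over 200 replicates at the emulated patient sample size n = 44. These
sizes were chosen so a complete run takes a few minutes on one CPU while
every recovered quantity keeps a comfortable margin over its threshold.

# Known limitations

* Single-subject ICA + HPM is quadratic in subjects for stage-1 matching
  and is not parallelized here.
* The Monte-Carlo extent calibration simulates Gaussian fields; at very
  small degrees of freedom the procedure is mildly anticonservative.
* Mediated (conditioning-drop) Granger indices at 140 volumes are too
  noisy for per-edge group inference; rely on the direct edges at cohort
  scale.
* Feature selection is not folded into cross-validation (see above); the
  reported accuracies are optimistic with respect to selection.
* The spatial model is rigid translation plus isotropic blobs; no
  subject-level shape variability.

# Worked example

```{r example, eval = FALSE}
library(icahpm)

spec <- cohortSpec(seed = 20L)          # the default study conditions
cohort <- generateCohort(spec)
pre <- lapply(cohort$subjects, function(s) preprocessSubject(s)$series)
ica <- lapply(pre, runSubjectICA, orders = enumerateModelOrders(10, 40),
              seed = 42L)
clusters <- runHPM(ica)                 # reproducible components
length(clusters)                        # 4: one per planted source

## or, equivalently, one call driven by a config:
report <- runPipeline(list(
  ica = list(orders = "10:40:10"),
  seed = 20L, outDir = "run1"))
```
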