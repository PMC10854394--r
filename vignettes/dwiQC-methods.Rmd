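---
title: "Motion-artifact QC for pediatric diffusion MRI: models and methods"
author: "dwiQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-artifact QC for pediatric diffusion MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the design choices behind `dwiQC`:
what is being modelled, which knobs matter, what the synthetic phantom can
and cannot stand in for, and where the numerically delicate corners are.

## The problem

A diffusion MRI exam is a series of 3D volumes, each sensitized to water
diffusion along one gradient direction at one b-value. Infants scanned
during natural sleep move; motion during the interleaved 2D-EPI readout
corrupts whole volumes, most visibly as *slice dropout* (one or more axial
slices losing signal) and *interleave* corruption (alternating slices
modulated, the "venetian blind" look). Quality control consists of
identifying corrupted volumes and removing them before model fitting.
`dwiQC` automates the per-volume decision with a 3D convolutional
classifier and then quantifies what that decision is worth downstream, by
fitting the diffusion tensor under three policies — no QC, reference
(manual) QC, model QC — and comparing the derived maps.

## The classifier

The network consumes a whole conformed volume (one channel) and emits a
single artifact probability:

* four feature-extraction blocks: 3D convolution (3 x 3 x 3 kernel, same
  padding, ReLU), 3D max pooling (size 2, stride 2, floor semantics on odd
  axes), batch normalisation, with filter counts 8, 16, 32, 64;
* flatten, dense(128, ReLU), dropout 0.5, dense(128, ReLU), dense(1,
  sigmoid).

At the default 128 x 128 x 70 input the spatial trace is 64 x 64 x 35 →
32 x 32 x 17 → 16 x 16 x 8 → 8 x 8 x 4, so the head sees 8·8·4·64 = 16 384
features. Batch normalisation is placed after pooling; whether activation
precedes or follows normalisation inside a block is a genuinely open
choice, and this package asserts the order conv → ReLU → pool → norm
rather than claiming it is the only reasonable graph. Convolution padding
is "same" so pooling is the only source of downsampling.

Training minimises binary cross-entropy with Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-7) at batch size 8 for a fixed number of epochs; there is no early
stopping and the final-epoch weights are the model. The initial learning
rate is 1e-3. "Learning-rate decay" is realised as a per-epoch
multiplicative factor of 0.9 — the schedule is a recorded, configurable
default rather than a claim. Weights are initialised from a seeded
fan-in-scaled Gaussian; data order, dropout masks and initialisation all
derive from the run seed, so a training run is exactly reproducible.

One network serves all shells: volumes of every b-value pass through the
same weights, which is what per-volume min–max normalisation to [0, 1] is
for — it puts b = 0 and high-b volumes on a common intensity scale.

Inference disables dropout and uses the stored running batch-norm
statistics, so predictions are deterministic; ties at the decision
threshold classify as artifact, because in QC the conservative error is
discarding a clean volume.

### The native engine

No deep-learning runtime is involved: the package carries its own C++
engine. Activations are float32, channel-major, with a one-voxel zero halo
so the 27-point convolution stencil needs no boundary tests; convolutions
run as register-blocked direct stencils (templated on channel width),
which outperforms im2col + GEMM by a large factor at these small channel
counts, and the few large dense products go through BLAS. Subnormal floats
are flushed to zero during training — tiny backpropagated gradients
otherwise hit the hardware denormal penalty. `src/Makevars` appends
`-O3 -march=native` (via `override`, since the composition of R's build
flags would otherwise pin a generic instruction set); the package is compiled on the
machine it runs on.

## Curation and splitting

Class imbalance is handled at the data level: per subject (pooling
sessions), all corrupted volumes are kept together with an equal number of
artifact-free volumes sampled uniformly without replacement; if more than
half (strictly) of a subject's volumes are corrupted, all are kept;
subjects with no corrupted volumes contribute nothing. The curated set is
therefore 50% artifact wherever the more-than-half rule did not fire.
b = 0 volumes are curated and labelled exactly like diffusion-weighted
volumes: near-identical b = 0 copies are precisely why splitting must
happen at the subject level, so folds are partitions of subjects (sizes
differing by at most one after a seeded shuffle) and all sessions travel
with their subject.

Conformation to the fixed grid is a centred zero-pad or crop per axis,
with odd remainders going to the high-index side — an arbitrary but fixed
convention that makes the operation bit-reproducible. A constant volume
normalises to all zeros rather than dividing by zero; a featureless
volume should look featureless.

## The synthetic phantom

The phantom exists so that every stage — curation, training, tensor
fitting, the QC-impact comparison — can be tested against known ground
truth. It is an ellipsoidal "brain" of isotropic tissue (eigenvalues
1.0 x 10^-3 mm^2/s) containing a corpus-callosum-like slab with
eigenvalues 1.7/0.2/0.2 x 10^-3 mm^2/s (closed-form FA 0.8704), plus an
isotropic control ball; both regions double as ROI masks, standing in for
atlas-derived regions without any registration machinery. Signals follow
the monoexponential tensor model S = S0·exp(−b gᵀDg) on a multi-shell
scheme mirroring the infant protocols the package targets (69 volumes at
b = 0/350/800/1500 s/mm², or 105 volumes at b = 0/300/800/1200/2500);
directions are a deterministic spherical-Fibonacci spread per shell.
Noise is Rician — the magnitude of a complex Gaussian perturbation, the
correct model for magnitude MRI — at a default SNR of 30 on S0; a
Gaussian option exists for analytic tests.

Artifacts are injected only along the axial (third) axis, matching the
slice-encoding physics of interleaved 2D-EPI. The default severity
distribution spans severe to subtle: a corrupted volume receives either
slice dropout (1 to nz/4 contiguous slices attenuated by a uniform factor
in [0, 0.5]) or interleave modulation (period 2, amplitude uniform in
[0.3, 0.8]), with equal probability. A rigid misalignment artifact
(rotation + translation, trilinear resampling, zero fill) is available
but not part of the default mixture, which targets the two slice-wise
phenomena the classifier is built for. The default per-volume corruption
prevalence is 0.11, the rate reported for the early-pediatric cohorts
this tool is aimed at. Between-subject variability (ellipsoid axes ±8%,
eigenvalues ±12%, S0 ±10%) gives the per-subject ROI means a genuine
spread, without which a concordance coefficient across subjects would be
meaningless.

What the phantom does *not* emulate: real anatomy and partial-volume
structure, susceptibility/eddy/ghosting artifacts, spatially correlated
noise, and rater ambiguity in the reference labels (simulator labels are
exact). A classifier that is near-perfect here will not be near-perfect
on scanner data; passing the synthetic benchmarks demonstrates that the
pipeline is implemented correctly and that the method can learn the
artifact phenomenology it targets, not that any particular real-data
accuracy is guaranteed.

## Study sizes

The reference synthetic benchmark is a 40-subject cohort of 69-volume
exams on a 64 x 64 x 36 grid (half the full acquisition resolution per
axis), curated to balance and cross-validated subject-wise with k = 4 for
10 epochs per fold; on one CPU this takes on the order of ten minutes and
reaches a mean held-out accuracy above 95%. The QC-impact study uses 12
subjects at prevalence 0.2 with dropout-only severity (attenuation
≤ 0.3), a regime in which uncorrected artifacts visibly bias FA. The
acceptance script scales the cross-validation cohort to 25 subjects to
keep its end-to-end runtime modest; with less training data per fold its
accuracy can sit somewhat below the 40-subject figure.

## Tensor fitting and the QC-impact analysis

The diffusion tensor is estimated per voxel from the log-linear model
ln S = ln S0 − b gᵀDg (seven parameters). An ordinary-least-squares pass
initialises a single reweighted solve with weights equal to the squared
predicted signals — the standard variance model for log-transformed
magnitude data; the one-step scheme is recorded and configurable
(`method = "ols"` skips it). Preconditions are enforced, not assumed: at
least seven volumes, at least one b = 0, and a design of full rank 7.
Non-positive signals, possible under heavy noise, are clipped to 1e-6 of
the voxel's mean b = 0 intensity before the log. Eigenvalues are sorted
descending; MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2, and
FA = √(3/2)·√(Σ(λᵢ−MD)²/Σλᵢ²), defined as 0 when all eigenvalues vanish.
FA is not clamped: values outside [0, 1] can only arise from
non-positive-definite fits and are informative.

Pipelines are compared two ways. Across subjects, Lin's concordance
correlation coefficient, CCC = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²) with
divisor-n moment estimators, measures agreement of per-subject ROI means
between the reference manual policy and each alternative; unlike a
Pearson correlation it also penalises location and scale shifts, which is
what makes it a reproducibility index. Within subjects, the model-QC and
no-QC ROI voxel values are compared with a Welch two-sample t-test on the
means and a two-sided F-test on the variance ratio. Welch's form is
chosen over the pooled t precisely because the companion F-test
contemplates unequal variances, and the two pipelines' values are treated
as independent samples since their voxel supports can differ.
Significance uses the Bonferroni-corrected threshold p < 0.05/3 ≈ 0.0167
(three metrics per region in the canonical analysis; the threshold is
applied per test regardless of how many of the four available maps are
requested). On synthetic data the "manual" arm uses the simulator's
ground-truth labels as the stand-in for a human reader.

## Decision-threshold calibration

The default decision threshold is 0.5. Because the artifact severity a
study tolerates is a judgment call, `tuneThreshold()` scans every
candidate threshold (midpoints between sorted distinct probabilities,
plus 0.5) on a labelled calibration set and optimises either balanced
accuracy or a minimum-false-negative objective under a false-positive
budget. Ties are broken toward the most *stable* threshold — the
candidate farthest from any observed probability, so a separating gap
yields its midpoint. Volumes whose probability falls within ε of the
chosen threshold are returned as "borderline" for human review; lowering
the threshold can only increase artifact sensitivity (TPR is monotone
non-increasing in the threshold, TNR non-decreasing — a property the test
suite asserts).

## Numerical and degenerate-input choices

* Max pooling uses floor semantics; a trailing odd plane is simply unused
  by that block.
* Batch-norm uses ε = 1e-5, biased batch variances, and running-statistic
  momentum 0.1; an untrained network predicts with the initial (0, 1)
  statistics.
* The engine's float32 arithmetic means two *different* builds can differ
  in the last ulp; determinism claims are within a build, where they are
  exact (same seed → identical weights, same volume → identical
  probability).
* Empty ROI extractions are flagged (warning + attribute), never silently
  empty; removing every volume of a shell during QC warns.
* Manifest volume indices are 0-based on disk and in memory.

## Known limitations

Binary volume-level QC only: no slice-level localisation, no artifact
typing, no outlier replacement. The phantom's geometric simplicity means
texture-based false-positive modes of real data are untested. The CLI
covers the synthetic workflow and single-exam prediction; orchestrating a
full real-data study (preprocessing, registration, atlas ROIs) is out of
scope, and the fitting stage deliberately reserves a slot for externally
computed maps (e.g. multi-compartment model outputs) rather than fitting
such models itself.
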