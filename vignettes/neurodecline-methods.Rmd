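---
title: "Modeling domain-level cognitive decline from multimodal neuroimaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling domain-level cognitive decline from multimodal neuroimaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurodecline)
```

## The problem

On the Alzheimer's disease continuum — cognitively normal (CN), mild
cognitive impairment (MCI), dementia — clinical progression is highly
heterogeneous. This package models **domain-level cognitive trajectories**
(memory, language, visuospatial abilities, executive function) from
multimodal neuroimaging: structural MRI tissue maps, FDG-PET metabolism,
and AV45-PET amyloid load, optionally combined with neuropsychological and
demographic information. Three prediction problems are supported per
domain: the *quantitative* annual rate of decline (a regression target),
the *qualitative* decliner/stable status (a binary target defined against
normative aging), and the clinical diagnosis at fixed horizons (2 and 4
years, a 3-class target).

Because the source data for studies of this kind are credentialed, the
package ships a seeded synthetic cohort generator that reproduces the
*statistical structure* the framework assumes — not real brains — so every
stage runs end to end at desk scale.

## Cognitive composites

Per domain, item scores from a neuropsychological battery are summarized
by a **one-factor measurement model** with the latent factor variance
fixed at 1 for identification. Timed items enter as the natural logarithm
of the completion time in seconds (the base is a free choice since the
transform is monotone either way) and are direction-flipped so that higher
always means better cognition. Items are standardized with statistics from
the fitting sample; loadings are sign-aligned after fitting.

Implementation notes and deliberate approximations:

* The full structural-equation treatment with a weighted least squares
  mean- and variance-adjusted estimator is replaced by a maximum-likelihood
  single-factor model (`stats::factanal`) on numerically-coded indicators;
  ordinal items are treated as continuous. What the package promises — and
  what its tests verify — is loading and score *recovery* on data with a
  true one-factor structure, not estimator equivalence with any specific
  SEM software. The estimator name is recorded in the fitted object.
* Scores are **Bartlett factor scores**. They are conditionally unbiased
  and, unlike regression (Thomson) scores, recover the factor *exactly*
  when indicators are noiseless — a property the test suite pins at
  correlation 1 within 1e-6.
* Degenerate inputs: with a singular item correlation matrix (noiseless
  indicators) the ML problem has no interior solution, and the fit falls
  back to the exact first-principal-component solution; two-item domains
  use the closed form loading = sqrt(r); single-item domains have loading
  1 and the composite is the standardized item.

Raw composites are rescaled by anchoring to two reference medians,

$$x_{adj} = \frac{x - P50_{dem}}{P50_{cn} - P50_{dem}} \cdot 100,$$

so 0 is the median of mild-dementia subjects and 100 the median of CN
subjects. Finally, scores are adjusted for age and education by
residualizing against a linear normative model fitted only on **normative
subjects** — cognitively normal at every visit with sustained
amyloid-negative status. (The source study's normative definition also
used CDR and MMSE cut-offs; the synthetic battery does not emulate those
instruments, so the cohort generator encodes normality through the
diagnosis path and the amyloid flag.) The adjusted score is the deviation,
in composite points, from the normative expectation at that age and
education.

Missing items are imputed before fitting: chained-equation imputation
(iterative regression sweeps) for ordinary low-missingness items, and a
single random-forest surrogate model — using the remaining items plus age,
sex, and education — for a designated high-missingness item (mirroring a
naming test available only in a subset of the source cohorts). Observed
cells are never altered.

## Decline targets

* **Slope**: the OLS slope of the adjusted composite against years since
  the neuroimaging acquisition t0, using all visits at or after t0. Fewer
  than two usable visits yields a missing (masked) target, not an error.
  Whether a fixed horizon should limit the visits is not determined by the
  protocol; all post-t0 visits are used.
* **Threshold**: the empirical 5th percentile of slopes in the normative
  sample, computed with the linear-interpolation (R type-7) convention;
  the convention is recorded in the result and pinned by an
  order-statistic oracle test.
* **Label**: *decliner* iff the slope falls strictly below the threshold
  (below the rate of 95% of controls); equality is *stable*.
* **Horizon diagnosis**: the diagnosis at the visit nearest to t0 + 2 (or
  4) years within a ±6-month window; no visit in the window means a masked
  label, and equidistant ties go to the earlier visit.
* **Standardization**: regression targets are winsorized at the training
  sample's 5th/95th percentiles (clipping, not case deletion, so every
  subject keeps a target), then z-scored with the post-trim training mean
  and SD. Trimming is per domain. The parameters are frozen and reused on
  validation/test values.

## Representations

All three representations inherit one fixed ROI order from the label
atlas (116 regions by default, the size of the AAL parcellation).

* **Tabular**: per ROI, MRI contributes GM and WM volumes (sum of tissue
  probability × voxel volume, mm³) and PET contributes the mean and
  standard deviation of SUVR (population denominator, pinned by the
  voxel-loop oracle test) — 232 features at 116 ROIs.
* **Volume**: MRI intensities are divided by the median value in the WM
  region, then every volume is downsampled ×2 per axis by trilinear
  interpolation evaluated at the centers of 2×2×2 blocks (equivalently
  block means — the cheapest continuous kernel; constants are preserved
  exactly).
* **Graph**: an undirected, unweighted graph over the ROIs whose edges are
  the nonzero off-diagonal entries (|Θᵢⱼ| > 1e-8 after standardization) of
  a graphical-lasso precision matrix estimated from ROI-mean FDG SUVR of
  CN/MCI subjects. The graphical lasso is implemented as the classic block
  coordinate descent with W = S + ρI (diagonal penalized); a fine-grid
  penalized-likelihood oracle pins the 2-variable case, and positive
  definiteness is asserted by Cholesky. λ ∈ {0.2, 0.3, 0.4} spans the
  range explored in the source protocol (0.3 is the package default).
  Node features are the ROI's 2 tabular statistics per modality (d = 6
  when all three modalities are stacked).

## Model zoo and fusion

The package carries its own compact neural-network engine (dense, 3D
convolution via im2col, instance/batch/graph normalization, max/average
pooling, GCN/GATv2/GIN message passing, multi-head attention, Adam), with
analytic backpropagation verified against central finite differences in
the test suite. No external deep-learning runtime is required.

Encoders (`buildEmbeddingModel`):

* **FFN** for tabular inputs (hidden widths, SiLU, batch norm, dropout).
* **CNN scaffold**: 4 blocks of conv3×3×3 → instance norm → ELU → conv →
  max-pool 2 → dropout with channel widths (8, 16, 32, 64). The published
  description of this 8-conv-layer scaffold leaves exact widths open;
  widths are configuration, not hard-coded.
* **3D DenseNet**: bottleneck blocks of (4, 6, 8) layers, growth rate 4,
  compression 1.0, instance normalization.
* **GNN**: 6 message-passing layers × 128 channels by default, graph
  normalization (feature standardization over nodes with learnable scale
  and shift; the learnable mean-scale parameter of the original
  formulation is fixed at 1), ELU, dropout 0.1, jumping-knowledge
  concatenation, mean or sum pooling. GAT layers use the modified (v2
  style) attention mechanism with self-loops, single-headed per layer.

**Fusion** (`buildFusionModel`): per-modality linear projections W_m map
frozen embeddings to a common width D = 16; the token stack (plus an
optional auxiliary token from a two-layer FFN over composites and
demographics) passes through a bare 8-head MHA layer — no positional
encoding, no residual/layer-norm wrapper, so mean-pooled output is
invariant to token order, a property the tests pin — then a four-layer
head (64, 48, 32, 16; SiLU; batch norm on the first four layers; dropout
in the first layer). Multiclass outputs are softmax probabilities.

**Pre-training head** (`buildPretrainHead`): the same trunk with the final
two layers (32, 16) replicated once per task.

## Training protocol

The masked multitask loss is a weighted sum (all weights 1) of per-task
means over *observed* entries only: binary cross-entropy, categorical
cross-entropy, and Huber loss with δ = 2.5. The per-task reduction is the
mean, keeping task magnitudes comparable under varying missingness; a task
with no observed entries in a batch contributes 0.

Splits are subject-level: modeling subjects 60/10/30 into
train/validation/test stratified by baseline diagnosis, and the
pre-training pool (all imaging subjects except modeling-test) 85/15 —
no test subject ever leaks into pre-training, and every fitted
preprocessing object carries a provenance record asserting it.

Optimization is Adam with the learning rate halved every 20% of the
total epochs (lr(e) = lr₀·0.5^⌊5e/E⌋) and early stopping when validation
loss fails to improve for ⌈0.1E⌉ consecutive epochs, restoring the best
weights. Fine-tuning trains only the projections, auxiliary encoder, MHA
and head — frozen encoder parameters are bitwise unchanged, which a test
asserts — and model selection keeps the epoch with the best validation
MCC (classification; computed at a train-prevalence-matched decision
threshold, since a fixed 0.5 cut degenerates under class imbalance, with
ties broken by validation loss) or explained variance (regression).

Desk-scale defaults: the pipeline fine-tunes for 16 epochs with dropout
0.3 in the fusion stage. Both deviate from the source protocol's larger
budgets and 0.1 dropout deliberately: the desk-scale fine-tuning sample
(~120 subjects) is a fraction of the original study's, and at that size
longer schedules and weak regularization overfit — the protocol itself
treats epochs and dropout as tunable hyperparameters.

## What the synthetic cohort emulates — and what it does not

One latent severity per subject drives everything: regional GM/FDG
decreases and AV45 increases in an "affected" ROI subset (piecewise
constant per ROI plus voxel noise), per-domain decline slopes drawn from
N(−0.3 − 6·severity, 0.8) points/year, and a monotone non-improving
CN→MCI→dementia path via severity thresholds (0.35, 0.7) with mild
progression (5%/year relative). Normative subjects (default 30%) have
severity below 0.15 and amyloid-negative status. Follow-up mirrors the
longitudinal structure of such studies: modeling subjects have 5–13
semiannual visits (2–6 years), pre-training-only subjects 1–6 visits and
possibly missing PET modalities. Item noise (SD 3 on a latent with
population SD ≈ 12) gives composite reliabilities around 0.9, typical of
multi-item cognitive composites. The atlas is a Voronoi partition of an
ellipsoid — contiguous, deterministic regions, not anatomy.

Passing tests on this cohort demonstrate that the pipeline recovers
*planted* signal through the full mapping → composite → target → train →
fuse chain. They do not demonstrate performance on real brains: the
generator has no scanner or site effects, no registration error, no
spatially correlated noise, no floor/ceiling effects beyond ordinal
binning, and a single severity axis where real disease has several.

## Numerical choices and degenerate inputs

* Percentiles: R type 7 everywhere a percentile is taken.
* Decliner rule: strictly below threshold; equality stable.
* Graphical-lasso edge tolerance 1e-8; convergence warning carries λ and
  the iteration count.
* MCC: generalized covariance (R_K) form; a zero denominator yields 0; a
  single observed class yields NA (undefined marker) for MCC/AUC.
* EV = 1 − Var(residual)/Var(truth); zero-variance truth is an error.
* AUC: rank-based (Mann-Whitney) with midranks for ties.
* Bootstrap CIs: 2000-replicate nonparametric percentile intervals by
  default (the interval method of the source tables is unstated).
* Learning curves default to 10 repeats at desk scale (the source used
  100), configurable up; the repeats are independently seeded.
* Sex is encoded {0, 1} in the auxiliary features, standardized with the
  training statistics like every other input.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full pipeline on a
300-subject cohort (200 modeling, 100 pre-training-only) with 16³ volumes
and a 116-ROI atlas, tabular FFN encoders for the three modalities, and a
2-point learning curve with 3 repeats; unit tests use 8³–32³ volumes and
10–116 ROIs. These sizes were chosen so a complete run takes minutes on a
laptop CPU while leaving every architectural component (CNN, GNN, MHA)
exercised by its own training smoke test.

## Known limitations

* Ordinal indicators are approximated as continuous in the measurement
  model; no polychoric correlations.
* The GAT implementation is single-headed per message-passing layer.
* GraphNorm's learnable mean-scale parameter is fixed at 1.
* Whether composite loadings should be re-estimated per visit is left as
  in the source: loadings are fixed from the full training sample.
* The learning-curve protocol fixes one configuration (no hyperparameter
  search), as in the source.
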