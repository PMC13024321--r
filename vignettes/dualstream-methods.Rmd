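---
title: "Dual-stream transformer modelling of fMRI time series and functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream transformer modelling of fMRI time series and functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI characterises a subject by the BOLD signal of R atlas
parcels (regions of interest, ROIs) over T time points, a matrix
$X \in \mathbb{R}^{T \times R}$. Two complementary views of this matrix drive
most classification work in connectomics: the *temporal* view — the raw
multivariate dynamics — and the *connectivity* view — the static Pearson
correlation matrix $\mathrm{PCC} \in \mathbb{R}^{R \times R}$ between ROI
pairs. Classifiers built on only one view discard the other's information.
`dualstream` implements a framework that encodes both views with separate
transformer encoders, aligns their representations in a shared embedding
space, and fuses them for subject-level classification (here: autism spectrum
disorder vs typically developing controls, labels 1/0), together with the
evaluation and attribution machinery such a model needs.

## Model

**Temporal stream.** Each time point (a length-R vector) is projected
linearly to $d_1$ dimensions; sinusoidal positional encodings are added; a
learnable [CLS] token is prepended; $L_1$ standard post-norm encoder layers
(multi-head self-attention, feed-forward, residual connections, layer
normalisation) are applied; the subject representation $h_1$ is the final
[CLS] embedding. Because the positional encodings are computed analytically,
series of any length pass through the same encoder.

**Connectivity stream.** The strict upper triangle of the correlation matrix
is flattened to a vector of length $D = R(R-1)/2$ (for the common 200-ROI
parcellation, $D = 19{,}900$), segmented into patches of `patch_len`
consecutive elements, linearly embedded to $d_2$ dimensions, and processed by
$L_2$ encoder layers; the representation $h_2$ is the layer-normalised mean
over patch outputs. The default `patch_len = 100` tiles $19{,}900$ into 199
patches exactly; for other atlases the final patch is zero-padded and the
padded positions are excluded from every loss.

**Masked-reconstruction pre-training.** The temporal encoder learns by
masking whole time points — a masking ratio drawn uniformly from
$[0.25, 0.5]$ per batch — and reconstructing them, with mean squared error
taken over masked entries only. The connectivity encoder masks a fixed
fraction (default 0.15) of vector elements, set to zero (the natural null
correlation), and reconstructs them. Reconstruction heads are single linear
maps, deliberately the lightest possible decoder so the encoder itself must
carry the information. Masked time points are represented by a learned mask
token substituted before the input projection (zero-filling is available via
`mask_input = "zero"`). The two pretext tasks share no parameters, so running
them as two independent loops is exactly equivalent to the combined weighted
objective `joint_pretrain_loss()` exposes.

**Contrastive alignment.** Each stream's feature passes through its own
two-layer projection head onto the unit sphere, and an InfoNCE objective
pulls the two projections of the same subject together while pushing apart
in-batch pairs from different subjects (temperature 0.07). Two design points
deserve note. First, the two heads cannot share weights — their inputs have
different dimensions ($d_1 \ne d_2$) — so each stream has its own head with
identical hidden/output sizes. Second, the default loss is the symmetrised
average of both retrieval directions (temporal→connectivity and the
reverse); the one-directional form is available with `direction = "t2p"`.
The symmetric form is strictly more informative and reduces the risk of
representation collapse. The denominator includes the positive pair. Four
freezing policies control whether the backbone encoders adapt during this
stage; the projection heads always train.

**Fusion and classification.** Both features are first aligned to a common
dimension $d_f$ by per-stream linear maps $\tilde h_i = W_i h_i + b_i$. Five
fusion operators are implemented:

* **concat** — $[\tilde h_1; \tilde h_2]$, dimension $2 d_f$;
* **gated** — $g = \sigma(\mathrm{MLP}([h_1; h_2]))$,
  $g \odot \tilde h_1 + (1-g) \odot \tilde h_2$ (an element-wise convex
  combination);
* **cross-attention** — bidirectional cross-attention with residual and
  layer norm, then a perceptron on the concatenated normalised streams;
* **bilinear** — a learned bilinear form of the raw features plus the
  aligned-feature residual, layer-normalised;
* **attention pooling** — scalar softmax weights over the two aligned
  features (a two-point simplex).

Where the operator equations reference the *raw* features ($h_i$, for the
gate input and the bilinear form) versus the *aligned* ones ($\tilde h_i$,
for the combination paths), the implementation follows the equations
literally. A cross-attention over single vectors is degenerate — the softmax
over one key is identically 1 — so the default single-token mode is kept
faithful to that definition and an optional multi-token mode
(`n_tokens > 1`) reshapes each aligned feature into tokens so the attention
becomes non-trivial. Both modes are tested. The fused feature feeds a
three-layer softmax classifier (widths 256, 64, 2) trained with
cross-entropy.

When the contrastive heads are enabled, fine-tuning and prediction route each
stream through its head before fusion, so the fusion input dimension is the
head output dimension; the default $d_f$ equals that dimension. Ablation
switches remove the heads (`use_heads = FALSE`), skip pre-training
(`pretrain = FALSE`), or keep a single backbone (`backbone = "tst1"` /
`"tst2"`), in which case the lone projected feature goes straight to the same
classifier.

## Training protocol

Adam with weight decay $10^{-4}$ throughout. Reference learning rates are
$10^{-4}$ for the two self-supervised stages and $5 \times 10^{-5}$ for
fine-tuning; at the desk scales used in the tests the fine-tuning rate is
raised (defaults in `train_dualstream()`) since the trainable modules are
orders of magnitude smaller. Validation AUC — not loss — is the model
selection criterion: fine-tuning checkpoints the best-validation-AUC
parameters, stops once `patience` epochs pass without improvement, and
restores the best checkpoint before evaluation. Every stage takes an explicit
seed and the full pipeline is a deterministic function of one master seed.

The published configuration freezes both encoders at fine-tuning and trains
only heads, fusion and classifier; the same source also reports its best
results with both encoders unfrozen and documents non-zero head updates. The
package therefore exposes the full policy grid (`freeze_policy()`,
`freeze_proj_heads`) rather than resolving that tension, and
`train_config()` defaults to the unfrozen-encoders setting reported as
optimal, while the pipeline helper uses the frozen, light-weight setting for
its desk-scale defaults.

**Evaluation.** `compute_metrics()` reports AUC (rank/Mann–Whitney
formulation, average ranks on ties), accuracy, sensitivity, specificity and
F1 at a 0.5 threshold. `loso_evaluate()` implements leave-one-site-out
cross-validation: each site is held out once, a model factory trains on the
remaining sites, and subject-level predictions aggregate sliding-window
predictions by majority vote. Window length and stride are configurable; the
default is a single full-length window, in which case voting reduces
bit-exactly to plain evaluation. Vote ties break toward the positive class
(sensitivity-preserving), and the subject-level score used for AUC is the
mean window probability, since vote counts are too coarse for ranking.
`compare_runs()` performs paired two-tailed t-tests over matched seeds with
Bonferroni correction; identical vectors are reported as "no difference"
(p = 1) and constant non-zero differences are flagged as degenerate rather
than silently producing p = NaN. `relative_parameter_change()` quantifies how
far fine-tuning moves a module: per-tensor Frobenius-norm ratio
$\lVert\theta' - \theta\rVert_F / (\lVert\theta\rVert_F + 10^{-12})$,
averaged over tensors — a scale-aware reading of "relative change" (an
unchanged module scores 0; doubling every non-zero tensor scores 1). The
definition is stated prominently because other readings (e.g. global norm
ratio) are defensible and yield different numbers.

## Gradient attribution

For the connectivity stream, the importance of connection $(i,j)$ is the
absolute gradient of the ASD logit with respect to the flattened correlation
entry, averaged over analysed samples, and scattered back to a symmetric
$R \times R$ matrix (zero diagonal) through the package's fixed edge
ordering. The correlation vector is treated as the independent variable: its
dependence on the time series is deliberately not chained. For the temporal
stream, gradients with respect to the raw series are aggregated over time
*first* (signed mean), then the absolute value is taken, then the sample
average — reading the defining formula literally; `abs_first = TRUE` provides
the alternative order, which cannot cancel opposing temporal contributions
(the test suite exhibits a case distinguishing the two). Which samples to
analyse is unspecified in the source; the package defaults to the held-out
test split and leaves the choice to the caller. `top_connections()` ranks
strict-upper-triangle entries descending with lexicographic (i, j)
tie-breaking, clipping over-long requests with a warning.

## The synthetic generator

Real multi-site cohorts cannot ship with a package, so `simulate_dataset()`
generates the smallest dataset family that makes every downstream stage
testable: two balanced diagnostic groups whose ROI signals are multivariate
normal with an identity correlation matrix except on a designated edge set
(all pairs among the first five ROIs by default), where the TD group has
correlation `base_r = 0.1` and the ASD group `base_r + delta_r` with
`delta_r = 0.5`. Temporal structure is an AR(1) filter applied *after* the
spatial correlation is imposed,
$x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\, e_t$ with
$e_t \sim N(0, \Sigma_{\text{group}})$, so the stationary marginal
covariance equals $\Sigma_{\text{group}}$ exactly and the implanted
instantaneous correlations are preserved in expectation. The default
$\phi = 0.5$ reflects the lag-1 autocorrelation of band-pass-filtered
(0.01–0.1 Hz) BOLD at typical repetition times. Sites are assigned
round-robin within class, so every pseudo-site contains both classes whenever
the cohort size permits; optional per-site mean offsets and variance scales
(default 0) exercise cross-site distribution shift. Should an edge-set /
correlation combination be infeasible, the matrix is repaired by
nearest-positive-definite projection, and the repair errors out if it moves
any target entry by more than 0.05.

What the generator does **not** emulate: haemodynamic response shapes,
scanner-specific noise spectra, head-motion artefacts, heterogeneous
per-site sample sizes, or graded effect sizes across many weak edges. Tests
passing on this family therefore demonstrate that the machinery — masking,
alignment, fusion, voting, attribution — behaves as specified on data whose
ground truth is known, not that the model reaches any particular accuracy on
real cohorts.

## Numerical core and choices

No deep-learning runtime is assumed: the encoders, heads, fusion operators
and classifier run on a small reverse-mode automatic-differentiation engine
(matrix-level tape) included in the package, whose every operation is checked
against central finite differences in the test suite. Further numerical
conventions:

* **Edge ordering.** The strict upper triangle is flattened row-major
  ((1,2), (1,3), …, (1,R), (2,3), …) — a convention, fixed once and shared by
  the encoder, the generator and the attribution code so edge↔index maps are
  deterministic. `flatten_upper()` accepts matrices symmetric to $10^{-6}$.
* **Masking granularity.** The temporal pretext masks whole time-point rows
  and averages the loss over all ROIs in those rows, consistent with both a
  per-time-point and per-entry reading of the objective.
* **Degenerate inputs.** Zero-variance ROI columns (which subsume the
  all-zero quality-control case) are rejected at load time with a warning
  per subject, and `compute_pcc()` errors rather than emitting NaN.
  Projection onto the unit sphere and the cross-entropy are epsilon-guarded.
* **Quality-control generalisation.** The all-zero-ROI exclusion rule is
  generalised to zero variance, since any constant column breaks the
  correlation regardless of its value.
* **Desk scales.** The heavier checks run a 120-subject cohort
  (20 ROIs, 100 time points; encoders $d_1 = 64, L_1 = 2$ and
  $d_2 = 64, L_2 = 1$, patches of 10 over $D = 190$) for the
  self-supervised stages and a 200-subject cohort for end-to-end
  discrimination — sizes chosen so the full suite runs comfortably on a
  single CPU while leaving every architectural element (multi-head
  attention, patching, padding, fusion) exercised at non-trivial size.

## Limitations

The package trains small transformers on a single CPU; it is a faithful,
testable implementation of the framework at desk scale, not a
high-performance training system. Real-data preprocessing (motion
correction, nuisance regression, parcellation) is out of scope — inputs are
already-parcellated matrices. The bilinear operator stores a full
$d_1 \times d_2 \times d_f$ form, which is fine at the package's scales but
would need a low-rank cap for large fused dimensions.
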