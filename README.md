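# dualstream

Dual-stream transformer modelling of fMRI time series and functional
connectivity, in pure R.

## The problem

Classifying subjects (e.g. autism spectrum disorder vs typically developing
controls) from resting-state fMRI usually starts from one of two views of the
same data: the raw ROI time series `X ∈ R^{T×R}` (temporal dynamics), or the
Pearson correlation matrix between ROI pairs (static functional
connectivity). Either view alone discards the other's information.
`dualstream` implements a two-phase framework that uses both:

1. **Self-supervised pre-training.** A *temporal* transformer encoder reads
   `X` (linear projection per time point, sinusoidal positional encodings, a
   learnable [CLS] token, `L1` encoder layers) and is trained to reconstruct
   randomly masked time points. A *connectivity* transformer encoder reads
   the flattened strict upper triangle of the correlation matrix
   (`D = R(R−1)/2`; 19,900 features for a 200-ROI atlas), segmented into
   patches, and reconstructs randomly masked correlation entries. Both
   objectives are masked mean-squared error over masked positions only.
2. **Contrastive alignment and supervised fine-tuning.** Per-stream
   projection heads map both features onto the unit sphere, and an InfoNCE
   objective (temperature 0.07) pulls the two views of the same subject
   together against in-batch negatives. The aligned features are then fused —
   concatenation, gating, cross-attention, bilinear pooling, or attention
   pooling — and a three-layer softmax classifier is fine-tuned with
   cross-entropy, early-stopped on validation AUC.

The package also provides a multi-site synthetic cohort generator with a
controlled group difference in connectivity (so the whole pipeline is
testable offline), stratified and leave-one-site-out evaluation with
sliding-window majority voting, multi-seed comparisons with paired t-tests
and Bonferroni correction, and gradient-based attribution: connection-level
importance `I_ij = E_x |∂f_ASD/∂PCC_ij|` and ROI-level importance
`I_k = E_x |T^{-1} Σ_t ∂f_ASD/∂X_{t,k}|`.

Everything runs on a small reverse-mode autodiff engine written in base R
(matrix-level tape), validated against finite differences in the test suite —
no deep-learning runtime is required.

## Worked example

```r
library(dualstream)

# a 60-subject, 12-ROI, 3-site cohort with a connectivity difference of 0.5
# implanted on the edges among the first 5 ROIs
cfg <- sim_config(n_subjects = 60, R = 12, T_len = 60, n_sites = 3,
                  delta_r = 0.5, base_r = 0.1, seed = 7)
sim <- simulate_dataset(cfg)
sp  <- split_dataset(sim$records, c(0.7, 0.1, 0.2), seed = 1)

fit <- train_dualstream(
  sp$train, sp$val,
  tst1_cfg = tst1_config(d1 = 32, L1 = 1, heads = 4, ff_dim = 64),
  tst2_cfg = tst2_config(d2 = 32, L2 = 1, heads = 4, ff_dim = 64,
                         patch_len = 10),
  head_hidden = 32, head_out = 16, d_f = 16,
  pretrain_epochs = 10, contrastive_epochs = 10, contrastive_lr = 1e-3,
  finetune_cfg = train_config(epochs = 30, patience = 10, lr = 1e-3,
                              freeze = freeze_policy("both")),
  seed = 1)

scores <- predict_scores(fit$model, sp$test)
labels <- vapply(sp$test, `[[`, 0L, "label")
round(unlist(compute_metrics(labels, scores)), 4)
#>         auc         acc sensitivity specificity          f1
#>      0.9722      0.5000      0.0000      1.0000      0.0000

round(range(scores), 3)
#> [1] 0.439 0.498

round(unlist(compute_metrics(labels, scores, threshold = median(scores))), 4)
#>         auc         acc sensitivity specificity          f1
#>      0.9722      0.8333      0.8333      0.8333      0.8333

rep <- importance_report(fit$model, sp$test, k = 3)
rep$top_connections
#>   i  j      score
#> 1 9 12 0.02604765
#> 2 7  9 0.02486753
#> 3 5 10 0.02393807
```

The model ranks the held-out subjects almost perfectly (AUC 0.97: one
ASD/TD pair is misordered), but at this miniature scale the checkpoint
selected on validation AUC leaves the probabilities compressed just below
0.5 — the fixed 0.5 threshold then predicts TD for everyone (sensitivity 0),
while the same scores cut at their median classify 10 of 12 subjects
correctly. AUC-based model selection optimises ranking, not calibration,
which is why the threshold is an explicit argument. The importance table from
a 12-subject average is noisy at this size; the test suite and the acceptance
script verify implanted-edge recovery properly on a 200-subject cohort with
a rank-sum statistic.

A thin command-line wrapper with `simulate` / `train` / `loso` / `explain`
subcommands is installed under `inst/exec/dualstream`.

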