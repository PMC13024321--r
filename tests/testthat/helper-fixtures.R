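# Shared fixtures and numeric helpers. Heavy objects (simulated cohorts,
# trained pipelines) are built once per session and memoised here so several
# test files can reuse them.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# central finite differences of a scalar-valued function of a matrix
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# small deterministic subject record
toy_record <- function(seed = 1, T_len = 20, R = 6, id = "s1",
                       label = 0L, site = "siteA") {
  set.seed(seed)
  subject_record(id, label, site, matrix(rnorm(T_len * R), T_len, R))
}

# tiny encoder configs used across unit tests
tiny_tst1_cfg <- function() tst1_config(d1 = 16L, L1 = 1L, heads = 4L,
                                        ff_dim = 32L, dropout = 0)
tiny_tst2_cfg <- function() tst2_config(d2 = 16L, L2 = 1L, heads = 4L,
                                        ff_dim = 32L, patch_len = 5L,
                                        dropout = 0)

# the small study cohort used by the self-supervised acceptance checks:
# 120 subjects, 20 ROIs, 100 time points, 3 pseudo-sites, implanted
# connectivity difference delta_r = 0.5 on the block of the first 5 ROIs
study_cohort_small <- function() {
  memo("cohort120", function() {
    sim <- simulate_dataset(sim_config(n_subjects = 120, R = 20, T_len = 100,
                                       n_sites = 3, delta_r = 0.5,
                                       base_r = 0.1, seed = 42))
    c(sim, list(split = split_dataset(sim$records, seed = 43)))
  })
}

# the larger cohort for end-to-end discrimination: 200 subjects
study_cohort_large <- function() {
  memo("cohort200", function() {
    sim <- simulate_dataset(sim_config(n_subjects = 200, R = 20, T_len = 100,
                                       n_sites = 3, delta_r = 0.5,
                                       base_r = 0.1, seed = 52))
    c(sim, list(split = split_dataset(sim$records, seed = 53)))
  })
}

# desk-scale encoder configs prescribed for the convergence checks
desk_tst1_cfg <- function() tst1_config(d1 = 64L, L1 = 2L, heads = 8L,
                                        ff_dim = 128L)
desk_tst2_cfg <- function() tst2_config(d2 = 64L, L2 = 1L, heads = 8L,
                                        ff_dim = 128L, patch_len = 10L)

# pre-trained encoders on the small cohort (30 epochs) with per-epoch
# validation losses; shared by the convergence and alignment checks
pretrained_small <- function() {
  memo("pretrained_small", function() {
    co <- study_cohort_small()
    tst1 <- tst1_init(20L, desk_tst1_cfg(), seed = 101)
    hist1 <- pretrain_tst1(tst1, co$split$train, epochs = 30L, lr = 1e-4,
                           val_records = co$split$val, seed = 102)
    tst2 <- tst2_init(190L, desk_tst2_cfg(), seed = 103)
    hist2 <- pretrain_tst2(tst2, co$split$train, epochs = 30L, lr = 1e-4,
                           val_records = co$split$val, seed = 104)
    list(tst1 = tst1, tst2 = tst2, hist1 = hist1, hist2 = hist2)
  })
}

# contrastive stage on top of the pre-trained encoders (20 epochs, both
# encoders unfrozen, heads always trained); report on held-out subjects
aligned_small <- function() {
  memo("aligned_small", function() {
    co <- study_cohort_small()
    pre <- pretrained_small()
    head1 <- proj_head_init(proj_head_config(64L, 256L, 128L), seed = 201)
    head2 <- proj_head_init(proj_head_config(64L, 256L, 128L), seed = 202)
    heldout <- c(co$split$val, co$split$test)
    rep <- run_contrastive_stage(pre$tst1, pre$tst2, head1, head2,
                                 co$split$train,
                                 policy = freeze_policy("none"),
                                 epochs = 20L, batch_size = 32L, lr = 1e-3,
                                 tau = 0.07, val_records = heldout,
                                 seed = 203)
    list(head1 = head1, head2 = head2, report = rep, heldout = heldout)
  })
}

# one fully trained pipeline per seed on the large cohort (dual backbone,
# attention-pooling fusion), plus the two single-backbone ablations
trained_pipeline <- function(seed, backbone = "dual") {
  memo(sprintf("pipe_%s_%d", backbone, seed), function() {
    co <- study_cohort_large()
    train_dualstream(
      co$split$train, co$split$val,
      tst1_cfg = desk_tst1_cfg(), tst2_cfg = desk_tst2_cfg(),
      head_hidden = 64L, head_out = 32L,
      fusion_method = "attention_pooling", d_f = 32L,
      pretrain_epochs = 6L, pretrain_lr = 3e-4,
      contrastive_epochs = 8L, contrastive_lr = 1e-3,
      finetune_cfg = train_config(epochs = 60L, patience = 20L, lr = 1e-3,
                                  freeze = freeze_policy("both")),
      backbone = backbone, seed = seed)
  })
}

test_auc <- function(fit) {
  co <- study_cohort_large()
  sc <- predict_scores(fit$model, co$split$test)
  compute_metrics(vapply(co$split$test, `[[`, 0L, "label"), sc)$auc
}
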