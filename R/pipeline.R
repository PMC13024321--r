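#' Train the full dual-stream pipeline
#'
#' Orchestrates the three stages — masked-reconstruction pre-training of both
#' encoders, contrastive alignment of the projection heads, and supervised
#' fine-tuning through a fusion operator — and returns the fitted model. The
#' switches expose the framework's ablation axes: `use_heads = FALSE` removes
#' the contrastive stage and its projection heads (raw encoder features feed
#' the fusion), `pretrain = FALSE` starts from randomly initialised encoders,
#' and `backbone` selects a single-stream variant whose lone (projected)
#' feature goes straight to the classifier.
#'
#' The whole pipeline is a deterministic function of `seed`: stage seeds are
#' derived from it, and each stage's RNG use is local.
#'
#' @param train_records,val_records training and validation subjects.
#' @param tst1_cfg,tst2_cfg encoder configurations.
#' @param head_hidden,head_out projection-head dimensions.
#' @param fusion_method one of the five fusion operators (ignored for single
#'   backbones).
#' @param d_f fused feature dimension.
#' @param pretrain logical: run masked-reconstruction pre-training.
#' @param pretrain_epochs,pretrain_lr pre-training settings (both encoders).
#' @param use_heads logical: contrastive projection heads (and stage).
#' @param contrastive_epochs,contrastive_policy,contrastive_lr,tau
#'   contrastive-stage settings.
#' @param finetune_cfg a [train_config()].
#' @param batch_size batch size for the two self-supervised stages.
#' @param classifier_hidden classifier layer widths.
#' @param backbone `"dual"` (default) or a single-stream ablation: `"tst1"`
#'   (temporal only) or `"tst2"` (connectivity only).
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return list with `model` (a [ds_model()]), per-stage reports
#'   (`pretrain_tst1`, `pretrain_tst2`, `contrastive`, `finetune`) and the
#'   pre-training parameter snapshots (`snap_pre`) used for
#'   relative-parameter-change analyses.
#' @export
train_dualstream <- function(train_records, val_records,
                             tst1_cfg = tst1_config(d1 = 64L, L1 = 2L,
                                                    ff_dim = 128L),
                             tst2_cfg = tst2_config(d2 = 64L, L2 = 1L,
                                                    ff_dim = 128L,
                                                    patch_len = 10L),
                             head_hidden = 64L, head_out = 32L,
                             fusion_method = "attention_pooling",
                             d_f = 32L,
                             pretrain = TRUE, pretrain_epochs = 30L,
                             pretrain_lr = 1e-4,
                             use_heads = TRUE, contrastive_epochs = 20L,
                             contrastive_policy = freeze_policy("none"),
                             contrastive_lr = 1e-4, tau = 0.07,
                             finetune_cfg = train_config(
                               epochs = 60L, patience = 20L, lr = 1e-3,
                               freeze = freeze_policy("both")),
                             batch_size = 32L,
                             classifier_hidden = c(256L, 64L, 2L),
                             backbone = c("dual", "tst1", "tst2"),
                             seed = 1L, verbose = FALSE) {
  backbone <- match.arg(backbone)
  base <- (as.integer(seed) %% 100000L) * 13L
  R <- ncol(train_records[[1L]]$series)
  D <- (R * (R - 1L)) %/% 2L
  need_x <- backbone != "tst2"
  need_p <- backbone != "tst1"

  tst1 <- if (need_x) tst1_init(R, tst1_cfg, seed = base + 1L)
  tst2 <- if (need_p) tst2_init(D, tst2_cfg, seed = base + 2L)

  rep_p1 <- rep_p2 <- NULL
  if (pretrain) {
    if (need_x) {
      if (verbose) message("pre-training temporal encoder ...")
      rep_p1 <- pretrain_tst1(tst1, train_records, epochs = pretrain_epochs,
                              batch_size = batch_size, lr = pretrain_lr,
                              val_records = val_records, seed = base + 3L,
                              verbose = verbose)
    }
    if (need_p) {
      if (verbose) message("pre-training connectivity encoder ...")
      rep_p2 <- pretrain_tst2(tst2, train_records, epochs = pretrain_epochs,
                              batch_size = batch_size, lr = pretrain_lr,
                              val_records = val_records, seed = base + 4L,
                              verbose = verbose)
    }
  }

  head1 <- head2 <- NULL
  rep_cl <- NULL
  if (use_heads) {
    if (need_x) {
      head1 <- proj_head_init(proj_head_config(tst1_cfg$d1, head_hidden,
                                               head_out), seed = base + 5L)
    }
    if (need_p) {
      head2 <- proj_head_init(proj_head_config(tst2_cfg$d2, head_hidden,
                                               head_out), seed = base + 6L)
    }
    if (backbone == "dual" && contrastive_epochs > 0L) {
      if (verbose) message("contrastive alignment ...")
      rep_cl <- run_contrastive_stage(tst1, tst2, head1, head2, train_records,
                                      policy = contrastive_policy,
                                      epochs = contrastive_epochs,
                                      batch_size = batch_size,
                                      lr = contrastive_lr, tau = tau,
                                      val_records = val_records,
                                      seed = base + 7L, verbose = verbose)
    }
  }

  feat1 <- if (use_heads) head_out else tst1_cfg$d1
  feat2 <- if (use_heads) head_out else tst2_cfg$d2
  fus_cfg <- fusion_config(
    method = if (backbone == "dual") fusion_method else "single",
    d_f = d_f, classifier_hidden = classifier_hidden)
  fm <- switch(backbone,
               dual = fusion_init(feat1, feat2, fus_cfg, seed = base + 8L),
               tst1 = fusion_init(feat1, 0L, fus_cfg, seed = base + 8L),
               tst2 = fusion_init(feat2, 0L, fus_cfg, seed = base + 8L))
  model <- ds_model(tst1, tst2, head1, head2, fm, use_heads = use_heads,
                    backbone = backbone)

  snap_pre <- list(
    tst1 = if (need_x) params_snapshot(tst1$params),
    tst2 = if (need_p) params_snapshot(tst2$params),
    head1 = if (use_heads && need_x) params_snapshot(head1$params),
    head2 = if (use_heads && need_p) params_snapshot(head2$params))

  if (verbose) message("fine-tuning ...")
  rep_ft <- finetune(model, train_records, val_records, finetune_cfg,
                     seed = base + 9L)

  list(model = model, pretrain_tst1 = rep_p1, pretrain_tst2 = rep_p2,
       contrastive = rep_cl, finetune = rep_ft, snap_pre = snap_pre)
}
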