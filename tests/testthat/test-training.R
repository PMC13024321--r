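# Training-protocol contracts on a deliberately tiny problem: freezing,
# determinism, early stopping and the LOSO partition/voting rules.

tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    sim <- simulate_dataset(sim_config(n_subjects = 36, R = 8, T_len = 30,
                                       n_sites = 3, delta_r = 0.6,
                                       base_r = 0.1, seed = 77))
    c(sim, list(split = split_dataset(sim$records, c(0.6, 0.2, 0.2),
                                      seed = 78)))
  })
}

tiny_model <- function(seed = 1L) {
  t1 <- tst1_init(8L, tiny_tst1_cfg(), seed = seed)
  t2 <- tst2_init(28L, tst2_config(d2 = 16, L2 = 1, heads = 4, ff_dim = 32,
                                   patch_len = 7, dropout = 0), seed = seed + 1L)
  h1 <- proj_head_init(proj_head_config(16L, 16L, 8L), seed = seed + 2L)
  h2 <- proj_head_init(proj_head_config(16L, 16L, 8L), seed = seed + 3L)
  fm <- fusion_init(8L, 8L, fusion_config("attention_pooling", d_f = 8L,
                                          classifier_hidden = c(16L, 8L, 2L),
                                          dropout = 0), seed = seed + 4L)
  ds_model(t1, t2, h1, h2, fm)
}

test_that("fine-tuning freeze contract: frozen modules never move", {
  ns <- asNamespace("dualstream")
  co <- tiny_cohort()
  m <- tiny_model(seed = 10)
  s_t1 <- ns$params_snapshot(m$tst1$params)
  s_t2 <- ns$params_snapshot(m$tst2$params)
  s_h1 <- ns$params_snapshot(m$head1$params)
  s_fu <- ns$params_snapshot(m$fusion$params)
  cfg <- train_config(epochs = 3, patience = 3, lr = 1e-3, batch_size = 8,
                      freeze = freeze_policy("both"), freeze_proj_heads = TRUE)
  finetune(m, co$split$train, co$split$val, cfg, seed = 11)
  expect_identical(ns$params_snapshot(m$tst1$params), s_t1)
  expect_identical(ns$params_snapshot(m$tst2$params), s_t2)
  expect_identical(ns$params_snapshot(m$head1$params), s_h1)
  expect_false(identical(ns$params_snapshot(m$fusion$params), s_fu))
  expect_equal(relative_parameter_change(s_t1, ns$params_snapshot(m$tst1$params)), 0)
})

test_that("all four freezing policies leave exactly the frozen modules fixed", {
  ns <- asNamespace("dualstream")
  co <- tiny_cohort()
  for (pol in c("both", "tst1", "tst2", "none")) {
    m <- tiny_model(seed = 20)
    s_t1 <- ns$params_snapshot(m$tst1$params)
    s_t2 <- ns$params_snapshot(m$tst2$params)
    cfg <- train_config(epochs = 2, patience = 2, lr = 1e-3, batch_size = 8,
                        freeze = freeze_policy(pol))
    finetune(m, co$split$train, co$split$val, cfg, seed = 21)
    t1_same <- identical(ns$params_snapshot(m$tst1$params), s_t1)
    t2_same <- identical(ns$params_snapshot(m$tst2$params), s_t2)
    expect_equal(t1_same, pol %in% c("both", "tst1"), label = pol)
    expect_equal(t2_same, pol %in% c("both", "tst2"), label = pol)
  }
})

test_that("fine-tuning is deterministic given seed and config", {
  co <- tiny_cohort()
  run <- function() {
    m <- tiny_model(seed = 30)
    finetune(m, co$split$train, co$split$val,
             train_config(epochs = 3, patience = 3, lr = 1e-3, batch_size = 8,
                          freeze = freeze_policy("both")), seed = 31)
    predict_scores(m, co$split$test)
  }
  expect_identical(run(), run())
})

test_that("early stopping never exceeds patience past the best epoch", {
  co <- tiny_cohort()
  m <- tiny_model(seed = 40)
  cfg <- train_config(epochs = 50, patience = 3, lr = 1e-3, batch_size = 8,
                      freeze = freeze_policy("both"))
  fit <- finetune(m, co$split$train, co$split$val, cfg, seed = 41)
  ran <- nrow(fit$history)
  expect_lte(ran - fit$best_epoch, cfg$patience)
  expect_equal(max(fit$history$val_auc), fit$best_val_auc)
  expect_error(finetune(m, co$split$train, list(), cfg), "empty validation")
})

test_that("LOSO folds are disjoint, exhaustive and site-pure", {
  co <- tiny_cohort()
  factory <- function(train_records, seed) {
    m <- tiny_model(seed = 50)
    sp <- split_dataset(train_records, c(0.8, 0.1, 0.1), seed = seed)
    finetune(m, sp$train, sp$val,
             train_config(epochs = 2, patience = 2, lr = 1e-3, batch_size = 8,
                          freeze = freeze_policy("both")), seed = seed)
    m
  }
  res <- loso_evaluate(co$records, factory, seed = 51)
  expect_equal(nrow(res$table), 3L)
  all_ids <- vapply(co$records, `[[`, "", "subject_id")
  sites <- vapply(co$records, `[[`, "", "site")
  for (s in res$table$site) {
    fold <- res$folds[[s]]
    expect_length(intersect(fold$train_ids, fold$test_ids), 0L)
    expect_setequal(c(fold$train_ids, fold$test_ids), all_ids)
    expect_setequal(fold$test_ids, all_ids[sites == s])
  }
})

test_that("majority voting: ties to positive, single window equals plain eval", {
  ns <- asNamespace("dualstream")
  # vote arithmetic: (ASD, ASD, TD) -> ASD; (ASD, TD) tie -> ASD
  votes <- function(wp) { n_pos <- sum(wp >= 0.5); as.integer(n_pos >= length(wp) - n_pos) }
  expect_equal(votes(c(0.9, 0.8, 0.2)), 1L)
  expect_equal(votes(c(0.9, 0.2)), 1L)
  expect_equal(votes(c(0.4, 0.2, 0.45)), 0L)

  co <- tiny_cohort()
  m <- tiny_model(seed = 60)
  factory <- function(train_records, seed) m
  res1 <- loso_evaluate(co$records, factory, seed = 61)            # 1 window
  res2 <- loso_evaluate(co$records, factory, seed = 61,
                        window_len = 1000L)                        # still 1
  expect_identical(res1$table, res2$table)
  # and the single-window scores equal plain per-subject evaluation
  s <- res1$table$site[1]
  fold <- res1$folds[[s]]
  sites <- vapply(co$records, `[[`, "", "site")
  plain <- predict_scores(m, co$records[sites == s])
  expect_identical(fold$scores, plain)
  expect_identical(fold$votes, as.integer(plain >= 0.5))

  # multi-window mode really aggregates several windows
  res3 <- loso_evaluate(co$records, factory, seed = 61,
                        window_len = 10L, window_stride = 10L)
  expect_equal(nrow(res3$table), 3L)
  expect_true(all(is.finite(res3$table$acc)))

  expect_error(loso_evaluate(co$records[sites == "site01"], factory),
               "at least 2 sites")
})

test_that("single-backbone models train and predict through the same head", {
  co <- tiny_cohort()
  t2 <- tst2_init(28L, tst2_config(d2 = 16, L2 = 1, heads = 4, ff_dim = 32,
                                   patch_len = 7, dropout = 0), seed = 70)
  fm <- fusion_init(16L, 0L, fusion_config("single", d_f = 16L,
                                           classifier_hidden = c(16L, 8L, 2L),
                                           dropout = 0), seed = 71)
  m <- ds_model(NULL, t2, fusion = fm, use_heads = FALSE, backbone = "tst2")
  fit <- finetune(m, co$split$train, co$split$val,
                  train_config(epochs = 5, patience = 5, lr = 1e-3,
                               batch_size = 8, freeze = freeze_policy("both")),
                  seed = 72)
  sc <- predict_scores(m, co$split$test)
  expect_length(sc, length(co$split$test))
  expect_true(all(sc >= 0 & sc <= 1))
})
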