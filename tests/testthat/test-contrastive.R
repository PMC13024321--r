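test_that("projection outputs live on the unit sphere", {
  head <- proj_head_init(proj_head_config(16L, 8L, 5L), seed = 1)
  set.seed(2)
  z <- project(head, rnorm(16))
  expect_length(z, 5L)
  expect_lt(abs(sqrt(sum(z^2)) - 1), 1e-6)
  # batch of rows: every row unit-norm
  Z <- project(head, matrix(rnorm(64), 4, 16))
  expect_true(all(abs(sqrt(rowSums(Z^2)) - 1) < 1e-6))
  # scaling the pre-normalisation activations by c > 0 leaves the normalised
  # output unchanged: double the last linear layer (weights and bias)
  x <- rnorm(16)
  z1 <- project(head, x)
  head$params[["proj.W2"]]$v <- head$params[["proj.W2"]]$v * 2
  head$params[["proj.b2"]]$v <- head$params[["proj.b2"]]$v * 2
  expect_equal(project(head, x), z1, tolerance = 1e-10)
  # zero input cannot produce NaN
  head0 <- proj_head_init(proj_head_config(4L, 4L, 3L), seed = 3)
  head0$params[["proj.W2"]]$v[] <- 0
  head0$params[["proj.b2"]]$v[] <- 0
  expect_true(all(is.finite(project(head0, rep(0, 4)))))
})

test_that("InfoNCE closed forms: identical embeddings, N = 1, two-pair geometry", {
  # all embeddings identical -> uniform softmax -> loss = log N, any tau
  for (N in c(2L, 4L, 8L)) {
    Z <- matrix(rep(c(1, 0, 0), each = N), N, 3)
    for (tau in c(0.05, 0.07, 0.5, 1)) {
      expect_equal(infonce_loss(Z, Z, tau), log(N), tolerance = 1e-12)
    }
  }
  # single pair: denominator is the positive alone -> loss 0
  z <- matrix(c(1, 0), 1, 2)
  expect_equal(infonce_loss(z, z, 0.07), 0)
  # two aligned pairs with orthogonal cross-terms: closed form within 1e-9
  tau <- 0.07
  Zt <- rbind(c(1, 0), c(0, 1))
  Zp <- rbind(c(1, 0), c(0, 1))
  expected <- log(1 + exp(-1 / tau))
  expect_lt(abs(infonce_loss(Zt, Zp, tau) - expected), 1e-9)
  expect_lt(abs(infonce_loss(Zt, Zp, tau, direction = "t2p") - expected),
            1e-9)
})

test_that("InfoNCE is non-negative and sharpens as tau decreases", {
  set.seed(5)
  # random unit embeddings
  rand_unit <- function(n, d) {
    Z <- matrix(rnorm(n * d), n, d)
    Z / sqrt(rowSums(Z^2))
  }
  for (k in 1:20) {
    Zt <- rand_unit(6, 8); Zp <- rand_unit(6, 8)
    expect_gte(infonce_loss(Zt, Zp, 0.2), 0)
  }
  # correctly aligned batch: loss non-increasing as tau decreases
  Zt <- rand_unit(8, 4)
  noise <- rand_unit(8, 4)
  Zp <- Zt + 0.1 * noise
  Zp <- Zp / sqrt(rowSums(Zp^2))
  taus <- c(1, 0.5, 0.2, 0.1, 0.07, 0.03)
  losses <- vapply(taus, function(t) infonce_loss(Zt, Zp, t), 0)
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("the tape-side InfoNCE agrees with the plain implementation", {
  ns <- asNamespace("dualstream")
  set.seed(7)
  Zt <- matrix(rnorm(20), 5, 4); Zt <- Zt / sqrt(rowSums(Zt^2))
  Zp <- matrix(rnorm(20), 5, 4); Zp <- Zp / sqrt(rowSums(Zp^2))
  ns$ag_reset()
  l_node <- ns$infonce_node(ns$ag_leaf(Zt), ns$ag_leaf(Zp), 0.07, "sym")
  expect_equal(as.numeric(l_node$v), infonce_loss(Zt, Zp, 0.07),
               tolerance = 1e-12)
  ns$ag_reset()
})

test_that("freezing contract: frozen encoders are bit-identical after the stage", {
  sim <- simulate_dataset(sim_config(n_subjects = 12, R = 6, T_len = 24,
                                     n_sites = 1, seed = 81))
  t1 <- tst1_init(6L, tiny_tst1_cfg(), seed = 11)
  t2 <- tst2_init(15L, tiny_tst2_cfg(), seed = 12)
  h1 <- proj_head_init(proj_head_config(16L, 8L, 8L), seed = 13)
  h2 <- proj_head_init(proj_head_config(16L, 8L, 8L), seed = 14)
  ns <- asNamespace("dualstream")
  s1 <- ns$params_snapshot(t1$params)
  s2 <- ns$params_snapshot(t2$params)
  sh <- ns$params_snapshot(h1$params)
  run_contrastive_stage(t1, t2, h1, h2, sim$records,
                        policy = freeze_policy("both"), epochs = 2,
                        batch_size = 6, seed = 15)
  expect_identical(ns$params_snapshot(t1$params), s1)
  expect_identical(ns$params_snapshot(t2$params), s2)
  # heads are always trained
  expect_false(identical(ns$params_snapshot(h1$params), sh))

  # unfreezing one encoder updates it and leaves the other untouched
  run_contrastive_stage(t1, t2, h1, h2, sim$records,
                        policy = freeze_policy("tst2"), epochs = 1,
                        batch_size = 6, seed = 16)
  expect_false(identical(ns$params_snapshot(t1$params), s1))
  expect_identical(ns$params_snapshot(t2$params), s2)

  expect_error(run_contrastive_stage(t1, t2, h1, h2, sim$records,
                                     policy = freeze_policy("both"),
                                     epochs = 1, batch_size = 1),
               "batch size")
})

test_that("initial contrastive loss sits near log(batch size) when softmax is near-uniform", {
  sim <- simulate_dataset(sim_config(n_subjects = 16, R = 6, T_len = 24,
                                     n_sites = 1, seed = 91))
  t1 <- tst1_init(6L, tiny_tst1_cfg(), seed = 21)
  t2 <- tst2_init(15L, tiny_tst2_cfg(), seed = 22)
  h1 <- proj_head_init(proj_head_config(16L, 8L, 8L), seed = 23)
  h2 <- proj_head_init(proj_head_config(16L, 8L, 8L), seed = 24)
  # at tau = 1 the temperature-scaled similarities of random heads are small,
  # the softmax is near-uniform, and the loss sits at log N
  rep1 <- run_contrastive_stage(t1, t2, h1, h2, sim$records,
                                policy = freeze_policy("both"), epochs = 1,
                                batch_size = 16, lr = 0, tau = 1, seed = 25)
  expect_lt(abs(rep1$loss[1] - log(16)), 0.5)
  # a sharp temperature amplifies the random similarity spread, so the
  # initial loss can only sit at or above that near-uniform level
  rep2 <- run_contrastive_stage(t1, t2, h1, h2, sim$records,
                                policy = freeze_policy("both"), epochs = 1,
                                batch_size = 16, lr = 0, tau = 0.07, seed = 25)
  expect_gte(rep2$loss[1], log(16) - 0.5)
  expect_true(is.finite(rep2$loss[1]))
})
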