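# Algebraic contracts of the five fusion operators.

mk_fusion <- function(method, d1 = 6L, d2 = 5L, d_f = 4L, seed = 1L,
                      n_tokens = 1L) {
  fusion_init(d1, d2, fusion_config(method, d_f = d_f,
                                    classifier_hidden = c(8L, 4L, 2L),
                                    dropout = 0, n_tokens = n_tokens),
              seed = seed)
}

test_that("alignment maps are linear with the right dimensions", {
  fm <- mk_fusion("concat")
  set.seed(2)
  h1 <- rnorm(6); h2 <- rnorm(5)
  al <- align_features(fm, h1, h2)
  expect_length(al$h1t, 4L)
  expect_length(al$h2t, 4L)
  # zero input with zero bias -> zero output
  fm$params[["align.b1"]]$v[] <- 0
  expect_equal(align_features(fm, rep(0, 6), h2)$h1t, rep(0, 4))
  # homogeneity when bias = 0
  a <- align_features(fm, h1, h2)$h1t
  expect_equal(align_features(fm, 3 * h1, h2)$h1t, 3 * a, tolerance = 1e-12)
})

test_that("concatenation embeds both aligned streams identically", {
  fm <- mk_fusion("concat")
  set.seed(3)
  h1 <- rnorm(6); h2 <- rnorm(5)
  al <- align_features(fm, h1, h2)
  fu <- fuse(fm, h1, h2)
  expect_length(fu$fused, 8L)
  expect_equal(fu$fused[1:4], al$h1t, tolerance = 1e-12)
  expect_equal(fu$fused[5:8], al$h2t, tolerance = 1e-12)
})

test_that("gated fusion is an element-wise convex combination", {
  fm <- mk_fusion("gated")
  set.seed(4)
  h1 <- rnorm(6); h2 <- rnorm(5)
  al <- align_features(fm, h1, h2)
  fu <- fuse(fm, h1, h2)
  g <- as.numeric(fu$extras$gate)
  expect_true(all(g > 0 & g < 1))
  expect_equal(fu$fused, g * al$h1t + (1 - g) * al$h2t, tolerance = 1e-10)
  lo <- pmin(al$h1t, al$h2t); hi <- pmax(al$h1t, al$h2t)
  expect_true(all(fu$fused >= lo - 1e-10 & fu$fused <= hi + 1e-10))

  # saturating the gate network recovers each stream exactly
  fm$params[["gate.W2"]]$v[] <- 0
  fm$params[["gate.b2"]]$v[] <- 50            # g -> 1
  expect_equal(fuse(fm, h1, h2)$fused, al$h1t, tolerance = 1e-8)
  fm$params[["gate.b2"]]$v[] <- -50           # g -> 0
  expect_equal(fuse(fm, h1, h2)$fused, al$h2t, tolerance = 1e-8)
  fm$params[["gate.b2"]]$v[] <- 0             # g = 0.5 -> element-wise mean
  expect_equal(fuse(fm, h1, h2)$fused, (al$h1t + al$h2t) / 2,
               tolerance = 1e-10)
})

test_that("cross-attention: single-token weights are exactly 1 and layer norms normalise", {
  fm <- mk_fusion("cross_attention")
  set.seed(5)
  h1 <- rnorm(6); h2 <- rnorm(5)
  fu <- fuse(fm, h1, h2, ln_affine = FALSE)
  expect_length(fu$fused, 4L)
  expect_equal(as.numeric(fu$extras$attn1[[1]]), 1)   # softmax of one key
  expect_equal(as.numeric(fu$extras$attn2[[1]]), 1)
  for (hp in c(fu$extras$h1p, fu$extras$h2p)) {
    expect_lt(abs(mean(hp)), 1e-4)
    expect_lt(abs(mean(hp^2) - 1), 1e-4)
  }
  # multi-token mode produces non-degenerate attention over 2 keys
  fm2 <- mk_fusion("cross_attention", n_tokens = 2L)
  fu2 <- fuse(fm2, h1, h2)
  A <- fu2$extras$attn1[[1]]
  expect_identical(dim(A), c(2L, 2L))
  expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
  expect_true(all(A > 0 & A < 1))
})

test_that("bilinear fusion is linear in each argument with zero bias", {
  fm <- mk_fusion("bilinear")
  fm$params[["bil.c"]]$v[] <- 0
  set.seed(6)
  h1 <- rnorm(6); h2 <- rnorm(5)
  b0 <- fuse(fm, h1, h2)
  expect_length(b0$fused, 4L)
  bil <- as.numeric(b0$extras$bilinear)
  # homogeneity in the first and second argument
  expect_equal(as.numeric(fuse(fm, 2.5 * h1, h2)$extras$bilinear), 2.5 * bil,
               tolerance = 1e-10)
  expect_equal(as.numeric(fuse(fm, h1, -3 * h2)$extras$bilinear), -3 * bil,
               tolerance = 1e-10)
  # additivity in the first argument
  g1 <- rnorm(6)
  expect_equal(as.numeric(fuse(fm, h1 + g1, h2)$extras$bilinear),
               bil + as.numeric(fuse(fm, g1, h2)$extras$bilinear),
               tolerance = 1e-10)
  # zero first argument kills the bilinear term; output is the normalised
  # residual
  z <- fuse(fm, rep(0, 6), h2, ln_affine = FALSE)
  expect_equal(as.numeric(z$extras$bilinear), rep(0, 4))
  r <- as.numeric(z$extras$residual)
  expect_equal(z$fused, (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5),
               tolerance = 1e-6)
})

test_that("attention pooling weights form a two-point simplex", {
  fm <- mk_fusion("attention_pooling")
  set.seed(7)
  for (k in 1:5) {
    h1 <- rnorm(6); h2 <- rnorm(5)
    fu <- fuse(fm, h1, h2)
    a <- as.numeric(fu$extras$alpha)
    expect_equal(sum(a), 1, tolerance = 1e-9)
    expect_true(all(a >= 0))
    al <- align_features(fm, h1, h2)
    expect_equal(fu$fused, a[1] * al$h1t + a[2] * al$h2t, tolerance = 1e-10)
    lo <- pmin(al$h1t, al$h2t); hi <- pmax(al$h1t, al$h2t)
    expect_true(all(fu$fused >= lo - 1e-9 & fu$fused <= hi + 1e-9))
  }
  # equal logits -> exact mean
  fm$params[["att.W2"]]$v[] <- 0
  fm$params[["att.b2"]]$v[] <- c(1, 1)
  h1 <- rnorm(6); h2 <- rnorm(5)
  al <- align_features(fm, h1, h2)
  expect_equal(fuse(fm, h1, h2)$fused, (al$h1t + al$h2t) / 2,
               tolerance = 1e-10)
  # saturated logits (+20, -20) -> first stream within 1e-6
  fm$params[["att.b2"]]$v[] <- c(20, -20)
  expect_equal(fuse(fm, h1, h2)$fused, al$h1t, tolerance = 1e-6)
})

test_that("all five operators honour a common contract", {
  set.seed(8)
  h1 <- rnorm(6); h2 <- rnorm(5)
  for (method in c("concat", "gated", "cross_attention", "bilinear",
                   "attention_pooling")) {
    fm <- mk_fusion(method)
    fu <- fuse(fm, h1, h2)
    expect_length(fu$fused, if (method == "concat") 8L else 4L)
    expect_true(all(is.finite(fu$fused)))
    pr <- classify(fm, fu$fused)
    expect_length(pr, 2L)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_identical(classify(fm, fu$fused), pr)   # eval-mode determinism
  }
})

test_that("cross-entropy loss follows its definition", {
  expect_equal(cls_loss(0, c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(cls_loss(1, c(0, 1)), 0, tolerance = 1e-9)
  expect_equal(cls_loss(1, c(0.9, 0.1)), -log(0.1), tolerance = 1e-6)
  # guarded against log(0)
  expect_true(is.finite(cls_loss(1, c(1, 0))))
})
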