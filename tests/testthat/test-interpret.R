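# Analytic surrogate models give exact expected gradients; they implement the
# same differentiable-logit hook as the real model.

ns <- asNamespace("dualstream")

# f_ASD = sum_e w_e p_e (linear in the connectivity vector)
lin_sur <- function(w) structure(list(w = w), class = "lin_sur")
registerS3method("asd_logit", "lin_sur", function(model, x = NULL, p = NULL) {
  ns$ag_sum(ns$ag_mul(p, ns$ag_leaf(matrix(model$w, nrow = 1))))
}, envir = asNamespace("dualstream"))

# f_ASD = p_e^2 for one edge index e
quad_sur <- function(e) structure(list(e = e), class = "quad_sur")
registerS3method("asd_logit", "quad_sur", function(model, x = NULL, p = NULL) {
  ns$ag_square(ns$ag_get(p, 1L, model$e))
}, envir = asNamespace("dualstream"))

# f_ASD = c * mean_t X[, k]
tmean_sur <- function(k, c) structure(list(k = k, c = c), class = "tmean_sur")
registerS3method("asd_logit", "tmean_sur", function(model, x = NULL, p = NULL) {
  ns$ag_scale(ns$ag_get(ns$ag_colmeans(x), 1L, model$k), model$c)
}, envir = asNamespace("dualstream"))

# f_ASD = X[1, k] - X[2, k] (cancelling temporal contributions)
tdiff_sur <- function(k) structure(list(k = k), class = "tdiff_sur")
registerS3method("asd_logit", "tdiff_sur", function(model, x = NULL, p = NULL) {
  ns$ag_sub(ns$ag_get(x, 1L, model$k), ns$ag_get(x, 2L, model$k))
}, envir = asNamespace("dualstream"))

# f_ASD ignores ROI k: column k is zeroed before a quadratic readout
drop_sur <- function(keep_w) structure(list(w = keep_w), class = "drop_sur")
registerS3method("asd_logit", "drop_sur", function(model, x = NULL, p = NULL) {
  xm <- ns$ag_mul(x, ns$ag_leaf(matrix(rep(model$w, each = nrow(x$v)),
                                       nrow(x$v))))
  ns$ag_sum(ns$ag_square(xm))
}, envir = asNamespace("dualstream"))

samples_R4 <- function(n = 3, T_len = 10) {
  lapply(seq_len(n), function(k) toy_record(seed = 40 + k, T_len = T_len,
                                            R = 4, id = paste0("s", k)))
}

test_that("connection importance of a linear readout is exactly |w|", {
  set.seed(12)
  w <- rnorm(6)                       # R = 4 -> D = 6
  conn <- connection_importance(lin_sur(w), samples_R4())
  expect_equal(dim(conn), c(4L, 4L))
  expect_equal(diag(conn), rep(0, 4))
  expect_equal(conn, t(conn))
  expect_equal(flatten_upper(conn), abs(w), tolerance = 1e-12)

  # sparse weights -> exactly that many nonzero entries above the diagonal
  w3 <- rep(0, 6); w3[c(1, 4, 6)] <- c(2, -1, 0.5)
  conn3 <- connection_importance(lin_sur(w3), samples_R4())
  expect_equal(sum(conn3[upper.tri(conn3)] != 0), 3L)
})

test_that("quadratic surrogate averages |2 p_e| over samples", {
  # samples with p_e in {-1, 0, 2} -> importance (2 + 0 + 4) / 3 = 2
  samples <- samples_R4()
  pe <- c(-1, 0, 2)
  for (k in 1:3) {
    samples[[k]]$pcc_vec <- c(pe[k], rep(0.1, 5))
  }
  conn <- connection_importance(quad_sur(1L), samples)
  expect_equal(conn[1, 2], 2, tolerance = 1e-12)
  expect_equal(sum(conn != 0), 2L)    # the edge and its mirror only
})

test_that("ROI importance distinguishes the two aggregation orders", {
  samples <- samples_R4(T_len = 3)
  # temporal-mean readout of ROI 3 with weight c = -1.7: each time point's
  # gradient is c/T, so the temporal mean of gradients is c/T and the
  # importance is |c|/T (hand evaluation of the defining formula)
  roi <- roi_importance(tmean_sur(3L, -1.7), samples)
  expect_equal(roi, c(0, 0, 1.7 / 3, 0), tolerance = 1e-12)
  # cancelling gradients (+1 at t=1, -1 at t=2): signed temporal mean is 0,
  # abs-first averages the magnitudes instead (2/T = 2/3)
  roi0 <- roi_importance(tdiff_sur(2L), samples)
  expect_equal(roi0, rep(0, 4), tolerance = 1e-12)
  roi_abs <- roi_importance(tdiff_sur(2L), samples, abs_first = TRUE)
  expect_equal(roi_abs, c(0, 2 / 3, 0, 0), tolerance = 1e-12)
})

test_that("a masked-out ROI has exactly zero importance", {
  roi <- roi_importance(drop_sur(c(1, 1, 0, 1)), samples_R4(), abs_first = TRUE)
  expect_equal(roi[3], 0)
  expect_true(all(roi[-3] > 0))
})

test_that("surrogate gradients match finite differences", {
  rec <- samples_R4(n = 1)[[1]]
  p0 <- flatten_upper(compute_pcc(rec$series))
  model <- lin_sur(rnorm(6))
  g_analytic <- ns$input_gradients(model, list(rec))[[1]]$gp
  f <- function(pv) {
    ns$ag_reset()
    v <- as.numeric(asd_logit(model, p = ns$ag_leaf(matrix(pv, nrow = 1)))$v)
    ns$ag_reset()
    v
  }
  expect_lt(max(abs(g_analytic - num_grad(f, matrix(p0, nrow = 1)))), 1e-6)
})

test_that("importance is invariant to sample order and errors on empty input", {
  set.seed(13)
  w <- rnorm(6)
  samples <- samples_R4()
  c1 <- connection_importance(lin_sur(w), samples)
  c2 <- connection_importance(lin_sur(w), rev(samples))
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_error(connection_importance(lin_sur(w), list()), "empty sample")
  expect_error(roi_importance(lin_sur(w), list()), "empty sample")
})

test_that("top connections are ranked with lexicographic tie-breaking", {
  m <- matrix(0, 4, 4)
  set_edge <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  m <- set_edge(m, 1, 2, 0.5)
  m <- set_edge(m, 1, 3, 0.9)
  m <- set_edge(m, 2, 4, 0.5)
  m <- set_edge(m, 3, 4, 0.2)
  tc <- top_connections(m, 3)
  expect_equal(tc$score, c(0.9, 0.5, 0.5))
  expect_equal(tc$i, c(1, 1, 2))       # tie (1,2) before (2,4)
  expect_equal(tc$j, c(3, 2, 4))

  # brute-force sort oracle on a random matrix
  set.seed(14)
  mm <- matrix(0, 5, 5)
  v <- runif(10)
  pr <- ns$upper_pairs(5)
  mm[pr] <- v; mm[pr[, c(2, 1)]] <- v
  tc2 <- top_connections(mm, 10)
  expect_equal(tc2$score, sort(v, decreasing = TRUE))

  expect_equal(nrow(top_connections(mm, 0)), 0L)
  expect_warning(tc3 <- top_connections(mm, 99), "clipped")
  expect_equal(nrow(tc3), 10L)
  # single nonzero edge ranks first
  m1 <- matrix(0, 4, 4); m1[2, 3] <- m1[3, 2] <- 1
  expect_equal(top_connections(m1, 1)[1, c("i", "j")],
               data.frame(i = 2, j = 3), ignore_attr = TRUE)
})
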