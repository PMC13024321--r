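#' Fusion and classification configuration
#'
#' The two stream features are first aligned to a common dimension `d_f` by
#' per-stream linear maps, then combined by one of five fusion operators:
#'
#' * `concat` — concatenation of the aligned features (length `2 d_f`);
#' * `gated` — element-wise convex combination with a sigmoid gate computed
#'   from the raw concatenated features;
#' * `cross_attention` — bidirectional cross-attention with residual
#'   connections and layer normalisation, followed by a perceptron on the
#'   concatenated normalised streams;
#' * `bilinear` — a learned bilinear form of the raw features, summed with the
#'   aligned-feature residual and layer-normalised;
#' * `attention_pooling` — a two-way softmax attention over the aligned
#'   features (scalar weights summing to 1).
#'
#' The fused feature feeds a three-layer softmax classifier.
#'
#' @param method fusion operator name (also `"single"` for a single-backbone
#'   model whose lone feature goes straight to the classifier).
#' @param d_f fused feature dimension.
#' @param classifier_hidden classifier layer widths, ending in the number of
#'   classes (2).
#' @param dropout classifier dropout rate during training.
#' @param n_tokens cross-attention token count: 1 (default) treats each
#'   aligned feature as a single token (the attention weight over the lone key
#'   is then exactly 1); larger values reshape each feature into `n_tokens`
#'   tokens of `d_f / n_tokens` so the attention is non-trivial.
#' @return a `fusion_config`.
#' @export
fusion_config <- function(method = c("concat", "gated", "cross_attention",
                                     "bilinear", "attention_pooling", "single"),
                          d_f = 128L, classifier_hidden = c(256L, 64L, 2L),
                          dropout = 0.3, n_tokens = 1L) {
  method <- match.arg(method)
  stopifnot(d_f > 0, classifier_hidden[length(classifier_hidden)] == 2L,
            d_f %% n_tokens == 0)
  structure(list(method = method, d_f = as.integer(d_f),
                 classifier_hidden = as.integer(classifier_hidden),
                 dropout = dropout, n_tokens = as.integer(n_tokens)),
            class = "fusion_config")
}

#' Initialise a fusion + classifier module
#'
#' @param d1_in,d2_in input feature dimensions of the two streams (for
#'   `method = "single"` only `d1_in` is used).
#' @param cfg a [fusion_config()].
#' @param seed integer seed.
#' @return a `fusion_model`.
#' @export
fusion_init <- function(d1_in, d2_in, cfg = fusion_config(), seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  p <- list()
  d_f <- cfg$d_f
  if (cfg$method != "single") {
    a1 <- init_linear(d1_in, d_f); a2 <- init_linear(d2_in, d_f)
    p[["align.W1"]] <- a1$W; p[["align.b1"]] <- a1$b
    p[["align.W2"]] <- a2$W; p[["align.b2"]] <- a2$b
  }
  if (cfg$method == "gated") {
    p <- c(p, new_mlp2(d1_in + d2_in, d_f, d_f, "gate."))
  } else if (cfg$method == "cross_attention") {
    dt <- d_f %/% cfg$n_tokens
    for (nm in c("q1", "k2", "v2", "q2", "k1", "v1")) {
      p[[paste0("ca.W", nm)]] <- init_linear(dt, dt)$W
    }
    p[["ca.ln1g"]] <- ag_leaf(matrix(1, 1, d_f))
    p[["ca.ln1b"]] <- ag_leaf(matrix(0, 1, d_f))
    p[["ca.ln2g"]] <- ag_leaf(matrix(1, 1, d_f))
    p[["ca.ln2b"]] <- ag_leaf(matrix(0, 1, d_f))
    p <- c(p, new_mlp2(2L * d_f, d_f, d_f, "camlp."))
  } else if (cfg$method == "bilinear") {
    s <- sqrt(6 / (d1_in * d2_in + d_f))
    p[["bil.B"]] <- ag_leaf(matrix(stats::runif(d1_in * d2_in * d_f, -s, s),
                                   d1_in * d2_in, d_f))
    p[["bil.c"]] <- ag_leaf(matrix(0, 1, d_f))
    p[["bil.lng"]] <- ag_leaf(matrix(1, 1, d_f))
    p[["bil.lnb"]] <- ag_leaf(matrix(0, 1, d_f))
  } else if (cfg$method == "attention_pooling") {
    p <- c(p, new_mlp2(2L * d_f, d_f, 2L, "att."))
  }
  in_dim <- switch(cfg$method,
                   concat = 2L * d_f,
                   single = d1_in,
                   d_f)
  dims <- c(in_dim, cfg$classifier_hidden)
  for (l in seq_len(length(dims) - 1L)) {
    lin <- init_linear(dims[l], dims[l + 1L])
    p[[sprintf("cls.W%d", l)]] <- lin$W
    p[[sprintf("cls.b%d", l)]] <- lin$b
  }
  structure(list(params = p, cfg = cfg, d1_in = as.integer(d1_in),
                 d2_in = as.integer(d2_in), n_cls_layers = length(dims) - 1L),
            class = "fusion_model")
}

# aligned features per Eq.-style linear maps; h1, h2 are B x d nodes
align_forward <- function(fm, h1, h2) {
  p <- fm$params
  list(h1t = ag_add(ag_matmul(h1, p[["align.W1"]]), p[["align.b1"]]),
       h2t = ag_add(ag_matmul(h2, p[["align.W2"]]), p[["align.b2"]]))
}

# one direction of cross attention for a single sample row (1 x d_f), token
# dimension dt = d_f / n_tokens; returns the 1 x d_f context and the attention
# matrix value
cross_attn_dir <- function(fm, hq, hkv, Wq, Wk, Wv) {
  dt <- fm$cfg$d_f %/% fm$cfg$n_tokens
  Qt <- ag_patchify(hq, dt)       # n_tokens x dt
  Kt <- ag_patchify(hkv, dt)
  Q <- ag_matmul(Qt, Wq); K <- ag_matmul(Kt, Wk); V <- ag_matmul(Kt, Wv)
  A <- ag_softmax_rows(ag_scale(ag_matmul(Q, ag_t(K)), 1 / sqrt(dt)))
  ctx <- ag_flatten_rows(ag_matmul(A, V))
  list(ctx = ctx, attn = A$v)
}

# Core fused-feature computation. h1, h2: B x d nodes. Returns list(fused,
# extras); extras carry gate / attention values for inspection.
fuse_forward <- function(fm, h1, h2, ln_affine = TRUE) {
  cfg <- fm$cfg
  p <- fm$params
  if (cfg$method == "single") {
    return(list(fused = h1, extras = list()))
  }
  al <- align_forward(fm, h1, h2)
  h1t <- al$h1t; h2t <- al$h2t
  if (cfg$method == "concat") {
    list(fused = ag_hstack(list(h1t, h2t)), extras = list())
  } else if (cfg$method == "gated") {
    g <- ag_sigmoid(mlp2_forward(p, "gate.", ag_hstack(list(h1, h2))))
    one_minus_g <- ag_shift(ag_scale(g, -1), 1)
    list(fused = ag_add(ag_mul(h1t, g), ag_mul(h2t, one_minus_g)),
         extras = list(gate = g$v))
  } else if (cfg$method == "cross_attention") {
    B <- nrow(h1t$v)
    rows <- vector("list", B)
    attn1 <- attn2 <- h1pv <- h2pv <- vector("list", B)
    for (b in seq_len(B)) {
      r1 <- ag_rows(h1t, b); r2 <- ag_rows(h2t, b)
      d1c <- cross_attn_dir(fm, r1, r2, p[["ca.Wq1"]], p[["ca.Wk2"]], p[["ca.Wv2"]])
      d2c <- cross_attn_dir(fm, r2, r1, p[["ca.Wq2"]], p[["ca.Wk1"]], p[["ca.Wv1"]])
      h1p <- if (ln_affine) {
        ag_layernorm_rows(ag_add(r1, d1c$ctx), p[["ca.ln1g"]], p[["ca.ln1b"]])
      } else ag_layernorm_rows(ag_add(r1, d1c$ctx))
      h2p <- if (ln_affine) {
        ag_layernorm_rows(ag_add(r2, d2c$ctx), p[["ca.ln2g"]], p[["ca.ln2b"]])
      } else ag_layernorm_rows(ag_add(r2, d2c$ctx))
      rows[[b]] <- ag_hstack(list(h1p, h2p))
      attn1[[b]] <- d1c$attn; attn2[[b]] <- d2c$attn
      h1pv[[b]] <- as.numeric(h1p$v); h2pv[[b]] <- as.numeric(h2p$v)
    }
    stacked <- if (B == 1L) rows[[1L]] else ag_vstack(rows)
    list(fused = mlp2_forward(p, "camlp.", stacked),
         extras = list(attn1 = attn1, attn2 = attn2,
                       h1p = h1pv, h2p = h2pv))
  } else if (cfg$method == "bilinear") {
    B <- nrow(h1$v)
    rows <- vector("list", B)
    for (b in seq_len(B)) {
      kron <- ag_vec_outer(ag_rows(h1, b), ag_rows(h2, b))
      rows[[b]] <- ag_add(ag_matmul(kron, p[["bil.B"]]), p[["bil.c"]])
    }
    bil <- if (B == 1L) rows[[1L]] else ag_vstack(rows)
    resid <- ag_add(h1t, h2t)
    pre <- ag_add(bil, resid)
    fused <- if (ln_affine) {
      ag_layernorm_rows(pre, p[["bil.lng"]], p[["bil.lnb"]])
    } else ag_layernorm_rows(pre)
    list(fused = fused, extras = list(bilinear = bil$v, residual = resid$v))
  } else { # attention_pooling
    logits <- mlp2_forward(p, "att.", ag_hstack(list(h1t, h2t)))
    alpha <- ag_softmax_rows(logits)
    a1 <- ag_cols(alpha, 1L); a2 <- ag_cols(alpha, 2L)
    list(fused = ag_add(ag_mul(h1t, a1), ag_mul(h2t, a2)),
         extras = list(alpha = alpha$v))
  }
}

classifier_forward <- function(fm, fused, train = FALSE) {
  x <- fused
  for (l in seq_len(fm$n_cls_layers)) {
    if (train && fm$cfg$dropout > 0) x <- ag_dropout(x, fm$cfg$dropout)
    x <- ag_add(ag_matmul(x, fm$params[[sprintf("cls.W%d", l)]]),
                fm$params[[sprintf("cls.b%d", l)]])
    if (l < fm$n_cls_layers) x <- ag_relu(x)
  }
  x
}

#' Align two stream features to the common fusion dimension
#'
#' @param fm a `fusion_model`.
#' @param h1,h2 numeric vectors (or row matrices) with the stream dimensions.
#' @return list with numeric `h1t`, `h2t`, both of length `d_f`.
#' @export
align_features <- function(fm, h1, h2) {
  ag_reset()
  al <- align_forward(fm, ag_leaf(h1), ag_leaf(h2))
  out <- list(h1t = drop1(al$h1t$v), h2t = drop1(al$h2t$v))
  ag_reset()
  out
}

drop1 <- function(v) if (nrow(v) == 1L) as.numeric(v) else v

#' Fuse two stream features
#'
#' Evaluation-mode application of the configured fusion operator.
#'
#' @param fm a `fusion_model`.
#' @param h1,h2 numeric vectors (or row matrices of a batch).
#' @param ln_affine apply learnable affine parameters inside the operator's
#'   layer norms (disable to expose raw normalised values in tests).
#' @return list with `fused` (numeric, length `2 d_f` for concat, `d_f`
#'   otherwise) and operator-specific `extras` (gate values, attention
#'   weights, bilinear/residual parts).
#' @export
fuse <- function(fm, h1, h2 = NULL, ln_affine = TRUE) {
  ag_reset()
  h1n <- ag_leaf(h1)
  h2n <- if (!is.null(h2)) ag_leaf(h2)
  out <- fuse_forward(fm, h1n, h2n, ln_affine = ln_affine)
  res <- list(fused = drop1(out$fused$v), extras = out$extras)
  ag_reset()
  res
}

#' Classify a fused feature
#'
#' @param fm a `fusion_model`.
#' @param fused numeric fused feature (or row matrix of a batch).
#' @return probability pair (TD, ASD) summing to 1 (or a matrix of such rows).
#' @export
classify <- function(fm, fused) {
  ag_reset()
  logits <- classifier_forward(fm, ag_leaf(fused), train = FALSE)
  lv <- logits$v
  ag_reset()
  e <- exp(lv - apply(lv, 1L, max))
  pr <- e / rowSums(e)
  colnames(pr) <- c("TD", "ASD")
  drop1(pr)
}

#' Cross-entropy classification loss
#'
#' `-sum_i y_i log(yhat_i)` for a one-hot true label, epsilon-guarded against
#' log(0).
#'
#' @param y true label: 0 (TD) or 1 (ASD).
#' @param probs probability pair (TD, ASD).
#' @param eps guard added inside the logarithm.
#' @return scalar loss.
#' @export
cls_loss <- function(y, probs, eps = 1e-12) {
  stopifnot(length(probs) == 2L, y %in% c(0, 1))
  -log(probs[[y + 1L]] + eps)
}
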