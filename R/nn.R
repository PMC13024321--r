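#' @title Transformer building blocks
#' @description Sinusoidal positional encodings, multi-head self-attention and
#' the standard post-norm encoder layer (attention -> add & norm ->
#' feed-forward -> add & norm), shared by the temporal and connectivity
#' encoders. All forward functions consume and return autodiff nodes.
#' @name nn-blocks
#' @keywords internal
NULL

# Standard sinusoidal positional encoding, n_pos x d (positions 0-based).
# Computed analytically, so sequences of any length are supported without
# re-instantiating the model.
sinusoidal_pe <- function(n_pos, d) {
  pos <- seq_len(n_pos) - 1
  i <- seq_len(ceiling(d / 2)) - 1
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(pos, freq)
  pe <- matrix(0, n_pos, d)
  pe[, 2 * i + 1] <- sin(ang)
  even <- 2 * i + 2
  even <- even[even <= d]
  pe[, even] <- cos(ang[, seq_along(even), drop = FALSE])
  pe
}

# Parameters of one encoder layer, as a flat named list with `prefix.`.
new_tf_layer <- function(d, ff_dim, prefix) {
  p <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    lin <- init_linear(d, d)
    p[[paste0(prefix, nm)]] <- lin$W
    p[[paste0(prefix, "b", substr(nm, 2, 2))]] <- lin$b
  }
  f1 <- init_linear(d, ff_dim)
  f2 <- init_linear(ff_dim, d)
  p[[paste0(prefix, "Wf1")]] <- f1$W
  p[[paste0(prefix, "bf1")]] <- f1$b
  p[[paste0(prefix, "Wf2")]] <- f2$W
  p[[paste0(prefix, "bf2")]] <- f2$b
  p[[paste0(prefix, "ln1g")]] <- ag_leaf(matrix(1, 1, d))
  p[[paste0(prefix, "ln1b")]] <- ag_leaf(matrix(0, 1, d))
  p[[paste0(prefix, "ln2g")]] <- ag_leaf(matrix(1, 1, d))
  p[[paste0(prefix, "ln2b")]] <- ag_leaf(matrix(0, 1, d))
  p
}

mha_forward <- function(prm, prefix, x, heads) {
  d <- ncol(x$v)
  dk <- d %/% heads
  Q <- ag_add(ag_matmul(x, prm[[paste0(prefix, "Wq")]]), prm[[paste0(prefix, "bq")]])
  K <- ag_add(ag_matmul(x, prm[[paste0(prefix, "Wk")]]), prm[[paste0(prefix, "bk")]])
  V <- ag_add(ag_matmul(x, prm[[paste0(prefix, "Wv")]]), prm[[paste0(prefix, "bv")]])
  outs <- vector("list", heads)
  sc <- 1 / sqrt(dk)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ag_cols(Q, idx); Kh <- ag_cols(K, idx); Vh <- ag_cols(V, idx)
    A <- ag_softmax_rows(ag_scale(ag_matmul(Qh, ag_t(Kh)), sc))
    outs[[h]] <- ag_matmul(A, Vh)
  }
  O <- if (heads == 1L) outs[[1L]] else ag_hstack(outs)
  ag_add(ag_matmul(O, prm[[paste0(prefix, "Wo")]]), prm[[paste0(prefix, "bo")]])
}

tf_layer_forward <- function(prm, prefix, x, heads, dropout = 0, train = FALSE) {
  a <- mha_forward(prm, prefix, x, heads)
  if (train && dropout > 0) a <- ag_dropout(a, dropout)
  x <- ag_layernorm_rows(ag_add(x, a),
                         prm[[paste0(prefix, "ln1g")]],
                         prm[[paste0(prefix, "ln1b")]])
  f <- ag_gelu(ag_add(ag_matmul(x, prm[[paste0(prefix, "Wf1")]]),
                      prm[[paste0(prefix, "bf1")]]))
  f <- ag_add(ag_matmul(f, prm[[paste0(prefix, "Wf2")]]),
              prm[[paste0(prefix, "bf2")]])
  if (train && dropout > 0) f <- ag_dropout(f, dropout)
  ag_layernorm_rows(ag_add(x, f),
                    prm[[paste0(prefix, "ln2g")]],
                    prm[[paste0(prefix, "ln2b")]])
}

# Two-layer perceptron parameters (in -> hidden -> out) under `prefix.`.
new_mlp2 <- function(d_in, d_hidden, d_out, prefix) {
  l1 <- init_linear(d_in, d_hidden)
  l2 <- init_linear(d_hidden, d_out)
  p <- list()
  p[[paste0(prefix, "W1")]] <- l1$W
  p[[paste0(prefix, "b1")]] <- l1$b
  p[[paste0(prefix, "W2")]] <- l2$W
  p[[paste0(prefix, "b2")]] <- l2$b
  p
}

mlp2_forward <- function(prm, prefix, x, act = ag_relu) {
  h <- act(ag_add(ag_matmul(x, prm[[paste0(prefix, "W1")]]),
                  prm[[paste0(prefix, "b1")]]))
  ag_add(ag_matmul(h, prm[[paste0(prefix, "W2")]]),
         prm[[paste0(prefix, "b2")]])
}
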