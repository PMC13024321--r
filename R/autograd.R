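#' @title Reverse-mode automatic differentiation core
#'
#' @description
#' A minimal matrix-level reverse-mode autodiff engine. Every differentiable
#' quantity is a node: an environment holding a numeric matrix `v`, an
#' accumulated gradient `g`, its parent nodes, and a backward closure that maps
#' the node's output gradient to gradients for its parents. Non-leaf nodes are
#' recorded on a tape in creation order, which is a valid topological order, so
#' the backward pass is a single reverse sweep. Leaves (parameters, inputs,
#' constants) live off-tape and simply accumulate gradients.
#'
#' The engine covers exactly the operations the encoders, projection heads,
#' fusion operators and classifier need: affine maps, attention (matmul,
#' row softmax, transpose, column slicing), layer normalisation, GELU/ReLU/
#' sigmoid/tanh, L2 row normalisation, masked mean-squared-error and
#' cross-entropy losses, patch reshaping and vectorised outer products.
#' Gradient correctness of each operation is established against central
#' finite differences in the test suite.
#'
#' @name autograd
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 4096L)
.ag$n <- 0L

#' Reset the autodiff tape
#'
#' Discards all recorded non-leaf nodes. Call at the start of each
#' forward/backward step; leaf parameters are unaffected.
#' @keywords internal
ag_reset <- function() {
  .ag$tape <- vector("list", 4096L)
  .ag$n <- 0L
  invisible(NULL)
}

as_row <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

#' Create a leaf node (parameter, input or constant)
#' @param v numeric matrix or vector (vectors become 1-row matrices)
#' @keywords internal
ag_leaf <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- as_row(v)
  e$g <- NULL
  e$leaf <- TRUE
  class(e) <- "agnode"
  e
}

is_agnode <- function(x) inherits(x, "agnode")

ag_node <- function(v, parents, bw) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$parents <- parents
  e$bw <- bw
  e$leaf <- FALSE
  class(e) <- "agnode"
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- e
  .ag$n <- n
  e
}

#' Backpropagate from a scalar (or any) node
#'
#' Seeds `root$g` with ones and sweeps the tape in reverse, accumulating
#' gradients into every contributing node, including off-tape leaves.
#' @keywords internal
ag_backward <- function(root) {
  root$g <- matrix(1, nrow(root$v), ncol(root$v))
  if (.ag$n == 0L) return(invisible(NULL))
  for (k in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[k]]
    if (is.null(nd$g)) next
    gs <- nd$bw(nd$g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(NULL)
}

#' Zero the gradients of a flat list of leaves
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- arithmetic -------------------------------------------------------------

# Addition with limited broadcasting: b may match a, be a 1-row bias, or 1x1.
ag_add <- function(a, b) {
  av <- a$v; bv <- b$v
  if (identical(dim(av), dim(bv))) {
    ag_node(av + bv, list(a, b), function(g) list(g, g))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_node(sweep(av, 2L, as.numeric(bv), "+"), list(a, b),
            function(g) list(g, matrix(colSums(g), nrow = 1L)))
  } else if (length(bv) == 1L) {
    ag_node(av + as.numeric(bv), list(a, b),
            function(g) list(g, matrix(sum(g), 1L, 1L)))
  } else {
    stop("ag_add: incompatible shapes")
  }
}

ag_sub <- function(a, b) {
  stopifnot(identical(dim(a$v), dim(b$v)))
  ag_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

# Elementwise product; b may be same-shape, a 1-row vector, or 1x1 scalar node.
ag_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  if (identical(dim(av), dim(bv))) {
    ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  } else if (length(bv) == 1L) {
    s <- as.numeric(bv)
    ag_node(av * s, list(a, b),
            function(g) list(g * s, matrix(sum(g * av), 1L, 1L)))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_node(sweep(av, 2L, as.numeric(bv), "*"), list(a, b),
            function(g) list(sweep(g, 2L, as.numeric(bv), "*"),
                             matrix(colSums(g * av), nrow = 1L)))
  } else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) {
    # per-row scalar weights (e.g. attention-pooling coefficients)
    s <- as.numeric(bv)
    ag_node(av * s, list(a, b),
            function(g) list(g * s, matrix(rowSums(g * av), ncol = 1L)))
  } else {
    stop("ag_mul: incompatible shapes")
  }
}

# Multiply / shift by plain numeric constants (not nodes).
ag_scale <- function(a, k) {
  ag_node(a$v * k, list(a), function(g) list(g * k))
}

ag_shift <- function(a, c) {
  ag_node(a$v + c, list(a), function(g) list(g))
}

ag_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

ag_t <- function(a) {
  ag_node(t(a$v), list(a), function(g) list(t(g)))
}

ag_square <- function(a) {
  av <- a$v
  ag_node(av * av, list(a), function(g) list(2 * g * av))
}

# ---- nonlinearities ---------------------------------------------------------

ag_relu <- function(a) {
  av <- a$v
  m <- av > 0
  ag_node(av * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$v))
  ag_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_tanh <- function(a) {
  y <- tanh(a$v)
  ag_node(y, list(a), function(g) list(g * (1 - y * y)))
}

# Exact GELU: x * Phi(x); derivative Phi(x) + x phi(x).
ag_gelu <- function(a) {
  av <- a$v
  ph <- stats::pnorm(av)
  ag_node(av * ph, list(a),
          function(g) list(g * (ph + av * stats::dnorm(av))))
}

# ---- structural ops ---------------------------------------------------------

ag_rows <- function(a, idx) {
  av <- a$v
  ag_node(av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

ag_cols <- function(a, idx) {
  av <- a$v
  ag_node(av[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, idx] <- g
    list(out)
  })
}

ag_get <- function(a, i, j) {
  ag_node(a$v[i, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    out[i, j] <- g
    list(out)
  })
}

ag_hstack <- function(nodes) {
  vs <- lapply(nodes, function(n) n$v)
  widths <- vapply(vs, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, vs), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ag_vstack <- function(nodes) {
  vs <- lapply(nodes, function(n) n$v)
  heights <- vapply(vs, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_node(do.call(rbind, vs), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# ---- reductions -------------------------------------------------------------

ag_sum <- function(a) {
  ag_node(matrix(sum(a$v), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(a$v), ncol(a$v)))
  })
}

ag_mean <- function(a) {
  n <- length(a$v)
  ag_node(matrix(mean(a$v), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / n, nrow(a$v), ncol(a$v)))
  })
}

ag_colmeans <- function(a) {
  m <- nrow(a$v)
  ag_node(matrix(colMeans(a$v), nrow = 1L), list(a), function(g) {
    list(matrix(rep(as.numeric(g) / m, each = m), nrow = m))
  })
}

# ---- composite layers -------------------------------------------------------

# Row softmax (used inside attention and attention pooling).
ag_softmax_rows <- function(a) {
  av <- a$v
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  y <- e / rowSums(e)
  ag_node(y, list(a), function(g) {
    dot <- rowSums(g * y)
    list((g - dot) * y)
  })
}

# Row-wise layer normalisation with optional learnable affine (gamma, beta are
# 1-row nodes or NULL to disable the affine transform, as used in tests).
ag_layernorm_rows <- function(x, gamma = NULL, beta = NULL, eps = 1e-5) {
  xv <- x$v
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  affine <- !is.null(gamma)
  yv <- if (affine) {
    sweep(sweep(xhat, 2L, as.numeric(gamma$v), "*"), 2L, as.numeric(beta$v), "+")
  } else xhat
  parents <- if (affine) list(x, gamma, beta) else list(x)
  ag_node(yv, parents, function(g) {
    gh <- if (affine) sweep(g, 2L, as.numeric(gamma$v), "*") else g
    t1 <- rowMeans(gh)
    t2 <- rowMeans(gh * xhat)
    dx <- (gh - t1 - xhat * t2) / sd_
    if (affine) {
      list(dx,
           matrix(colSums(g * xhat), nrow = 1L),
           matrix(colSums(g), nrow = 1L))
    } else {
      list(dx)
    }
  })
}

# Row-wise L2 normalisation onto the unit sphere, epsilon-guarded so a zero
# vector maps to zero rather than NaN.
ag_l2normalize_rows <- function(x, eps = 1e-12) {
  xv <- x$v
  nrm <- sqrt(rowSums(xv * xv) + eps)
  y <- xv / nrm
  ag_node(y, list(x), function(g) {
    dot <- rowSums(g * y)
    list((g - y * dot) / nrm)
  })
}

# Inverted dropout; identity when p = 0.
ag_dropout <- function(x, p) {
  if (p <= 0) return(x)
  mask <- matrix(stats::rbinom(length(x$v), 1L, 1 - p), nrow(x$v)) / (1 - p)
  ag_node(x$v * mask, list(x), function(g) list(g * mask))
}

# ---- losses -----------------------------------------------------------------

# Mean squared error over the TRUE entries of a logical mask; the reference
# matrix is a plain constant. Gradient is exactly zero off-mask.
ag_mse_masked <- function(xhat, x_ref, mask) {
  stopifnot(identical(dim(xhat$v), dim(x_ref)), identical(dim(mask), dim(x_ref)))
  nm <- sum(mask)
  if (nm == 0) stop("empty mask in masked MSE")
  r <- (xhat$v - x_ref) * mask
  ag_node(matrix(sum(r * r) / nm, 1L, 1L), list(xhat), function(g) {
    list(2 * r / nm * as.numeric(g))
  })
}

# Mean cross-entropy of row logits against integer class targets (1-based),
# computed with the log-sum-exp trick.
ag_ce_logits <- function(logits, targets) {
  lv <- logits$v
  m <- nrow(lv)
  stopifnot(length(targets) == m)
  mx <- apply(lv, 1L, max)
  lse <- mx + log(rowSums(exp(lv - mx)))
  picked <- lv[cbind(seq_len(m), targets)]
  loss <- mean(lse - picked)
  p <- exp(lv - lse)
  ag_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    d <- p
    d[cbind(seq_len(m), targets)] <- d[cbind(seq_len(m), targets)] - 1
    list(d / m * as.numeric(g))
  })
}

# ---- reshaping for the connectivity stream ----------------------------------

# Split a 1 x D row vector into N rows of patch_len, zero-padding the tail.
ag_patchify <- function(vec, patch_len) {
  v <- as.numeric(vec$v)
  D <- length(v)
  N <- ceiling(D / patch_len)
  pad <- N * patch_len - D
  ag_node(matrix(c(v, numeric(pad)), nrow = N, byrow = TRUE), list(vec),
          function(g) {
            flat <- as.numeric(t(g))
            list(matrix(flat[seq_len(D)], nrow = 1L))
          })
}

# Row-major flattening of an N x L matrix into 1 x (N*L); inverse of
# ag_patchify when there is no padding.
ag_flatten_rows <- function(m) {
  N <- nrow(m$v); L <- ncol(m$v)
  ag_node(matrix(as.numeric(t(m$v)), nrow = 1L), list(m), function(g) {
    list(matrix(as.numeric(g), nrow = N, byrow = TRUE))
  })
}

# Vectorised outer product: a (1 x p), b (1 x q) -> 1 x (p*q), column-major in
# (i, j): entry i + (j-1)p equals a_i * b_j. Backbone of the bilinear fusion.
ag_vec_outer <- function(a, b) {
  av <- as.numeric(a$v); bv <- as.numeric(b$v)
  p <- length(av); q <- length(bv)
  O <- outer(av, bv)
  ag_node(matrix(as.numeric(O), nrow = 1L), list(a, b), function(g) {
    Gm <- matrix(as.numeric(g), nrow = p)
    list(matrix(as.numeric(Gm %*% bv), nrow = 1L),
         matrix(as.numeric(crossprod(Gm, av)), nrow = 1L))
  })
}

# ---- optimiser --------------------------------------------------------------

#' Adam optimiser state for a flat named list of parameter leaves
#' @keywords internal
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p$v * 0),
    v = lapply(params, function(p) p$v * 0),
    t = 0L
  )
}

#' One Adam update step (classic L2 weight decay added to the gradient)
#' @keywords internal
adam_step <- function(params, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$g
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$v
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Xavier-uniform linear layer initialisation.
init_linear <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  list(W = ag_leaf(matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)),
       b = ag_leaf(matrix(0, 1L, fan_out)))
}

# Snapshot / restore raw parameter values (used for checkpointing on best
# validation AUC and for freeze-contract checks).
params_snapshot <- function(params) lapply(params, function(p) p$v)

params_restore <- function(params, snap) {
  for (k in seq_along(params)) params[[k]]$v <- snap[[k]]
  invisible(NULL)
}
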