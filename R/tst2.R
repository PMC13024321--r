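#' Configuration of the connectivity-stream encoder
#'
#' The connectivity encoder is an encoder-only transformer over the flattened
#' upper-triangular Pearson correlation vector. The vector is segmented into
#' patches of `patch_len` consecutive elements (the final patch zero-padded),
#' each patch is linearly embedded to `d2` dimensions, positional encodings
#' are added and `L2` encoder layers applied; the subject representation is
#' the layer-normalised mean over patch outputs. Pre-training masks a fixed
#' fraction `m2` of vector elements (set to zero, the null correlation) and
#' reconstructs them.
#'
#' @param d2 model dimension (divisible by `heads`).
#' @param L2 number of encoder layers.
#' @param heads attention heads.
#' @param ff_dim feed-forward hidden dimension.
#' @param dropout dropout rate during training.
#' @param patch_len elements per patch. The default 100 tiles the
#'   19,900-element vector of a 200-ROI atlas into 199 patches exactly.
#' @param m2 mask ratio for pre-training, in (0, 1).
#' @return a `tst2_config` list.
#' @export
tst2_config <- function(d2 = 256L, L2 = 2L, heads = 8L, ff_dim = 512L,
                        dropout = 0.1, patch_len = 100L, m2 = 0.15) {
  stopifnot(d2 %% heads == 0, patch_len >= 1, m2 > 0, m2 < 1)
  structure(list(d2 = as.integer(d2), L2 = as.integer(L2),
                 heads = as.integer(heads), ff_dim = as.integer(ff_dim),
                 dropout = dropout, patch_len = as.integer(patch_len),
                 m2 = m2),
            class = "tst2_config")
}

#' Segment a connectivity vector into patches
#'
#' @param vec numeric vector of length D.
#' @param patch_len elements per patch (or a [tst2_config()]).
#' @return list with `patches` (N x patch_len matrix, row-major fill,
#'   zero-padded tail), `D`, `n_pad`, and `real` (logical N x patch_len matrix
#'   marking non-pad positions).
#' @export
patchify <- function(vec, patch_len) {
  if (inherits(patch_len, "tst2_config")) patch_len <- patch_len$patch_len
  D <- length(vec)
  N <- ceiling(D / patch_len)
  n_pad <- N * patch_len - D
  patches <- matrix(c(as.numeric(vec), numeric(n_pad)), nrow = N, byrow = TRUE)
  real <- matrix(c(rep(TRUE, D), rep(FALSE, n_pad)), nrow = N, byrow = TRUE)
  list(patches = patches, D = D, n_pad = n_pad, real = real)
}

#' Restore a connectivity vector from its patches
#'
#' Exact inverse of [patchify()]: drops the zero padding.
#'
#' @param patches N x patch_len matrix (or the list returned by [patchify()]).
#' @param D original vector length (unneeded when a patchify list is given).
#' @return numeric vector of length D.
#' @export
depatchify <- function(patches, D = NULL) {
  if (is.list(patches)) {
    D <- patches$D
    patches <- patches$patches
  }
  stopifnot(!is.null(D))
  as.numeric(t(patches))[seq_len(D)]
}

#' Initialise a connectivity-stream encoder
#'
#' @param D connectivity vector length, R(R-1)/2.
#' @param cfg a [tst2_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `tst2_model`.
#' @export
tst2_init <- function(D, cfg = tst2_config(), seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  p <- list()
  emb <- init_linear(cfg$patch_len, cfg$d2)
  p[["emb.W"]] <- emb$W
  p[["emb.b"]] <- emb$b
  for (l in seq_len(cfg$L2)) {
    p <- c(p, new_tf_layer(cfg$d2, cfg$ff_dim, sprintf("l%d.", l)))
  }
  p[["pool.lng"]] <- ag_leaf(matrix(1, 1, cfg$d2))
  p[["pool.lnb"]] <- ag_leaf(matrix(0, 1, cfg$d2))
  dec <- init_linear(cfg$d2, cfg$patch_len)
  p[["dec.W"]] <- dec$W
  p[["dec.b"]] <- dec$b
  structure(list(params = p, cfg = cfg, D = as.integer(D)),
            class = "tst2_model")
}

# Forward pass on the tape. `p` is a length-D numeric vector or a 1 x D agnode
# (for gradient attribution). Masked elements are zeroed before patch
# embedding (zero being the natural null correlation). `ln_affine = FALSE`
# disables the learnable affine of the output layer norm (test hook).
tst2_forward <- function(model, p, mask_idx = NULL, train = FALSE,
                         ln_affine = TRUE) {
  cfg <- model$cfg
  prm <- model$params
  pn <- if (is_agnode(p)) p else ag_leaf(matrix(as.numeric(p), nrow = 1L))
  if (ncol(pn$v) != model$D) {
    stop("connectivity vector length ", ncol(pn$v),
         "; encoder expects ", model$D)
  }
  if (!is.null(mask_idx)) {
    keep <- rep(1, model$D)
    keep[mask_idx] <- 0
    pn <- ag_mul(pn, ag_leaf(matrix(keep, nrow = 1L)))
  }
  P <- ag_patchify(pn, cfg$patch_len)
  N <- nrow(P$v)
  z <- ag_add(ag_matmul(P, prm[["emb.W"]]), prm[["emb.b"]])
  z <- ag_add(z, ag_leaf(sinusoidal_pe(N, cfg$d2)))
  if (train && cfg$dropout > 0) z <- ag_dropout(z, cfg$dropout)
  for (l in seq_len(cfg$L2)) {
    z <- tf_layer_forward(prm, sprintf("l%d.", l), z, cfg$heads,
                          cfg$dropout, train)
  }
  pooled <- ag_colmeans(z)
  h <- if (ln_affine) {
    ag_layernorm_rows(pooled, prm[["pool.lng"]], prm[["pool.lnb"]])
  } else {
    ag_layernorm_rows(pooled)
  }
  phat_mat <- ag_add(ag_matmul(z, prm[["dec.W"]]), prm[["dec.b"]])
  list(h = h, phat_mat = phat_mat, N = N)
}

#' Encode a connectivity vector into the connectivity-stream representation
#'
#' Evaluation-mode forward pass; returns the pooled, layer-normalised patch
#' representation.
#'
#' @param model a `tst2_model`.
#' @param vec numeric connectivity vector of length D.
#' @param ln_affine apply the learnable affine of the output layer norm
#'   (disable to expose the raw normalised vector, e.g. in tests).
#' @return numeric vector of length `d2`.
#' @export
encode_pcc <- function(model, vec, ln_affine = TRUE) {
  ag_reset()
  out <- tst2_forward(model, vec, train = FALSE, ln_affine = ln_affine)
  v <- as.numeric(out$h$v)
  ag_reset()
  v
}

#' Sample element indices to mask in a connectivity vector
#'
#' @param D vector length.
#' @param m2 mask ratio in (0, 1).
#' @param seed integer seed.
#' @return sorted integer vector of `round(m2 * D)` distinct 1-based indices.
#' @export
sample_pcc_mask <- function(D, m2 = 0.15, seed = 1L) {
  stopifnot(m2 > 0, m2 < 1)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  k <- max(1L, round(m2 * D))
  sort(sample.int(D, k))
}

#' Masked reconstruction loss for the connectivity stream
#'
#' Mean squared error over the masked vector elements only.
#'
#' @param p original connectivity vector.
#' @param p_hat reconstructed vector.
#' @param mask_idx integer indices of masked elements.
#' @return scalar loss.
#' @export
pcc_recon_loss <- function(p, p_hat, mask_idx) {
  if (length(mask_idx) == 0L) stop("empty mask")
  stopifnot(length(p) == length(p_hat),
            all(mask_idx >= 1L), all(mask_idx <= length(p)))
  mean((p[mask_idx] - p_hat[mask_idx])^2)
}

#' Combined pre-training loss of the two streams
#'
#' Weighted sum of the temporal and connectivity reconstruction losses,
#' `l_roi + lambda * l_pcc`. With the default independent pre-training loops
#' the two terms are optimised separately (no shared parameters), which is
#' equivalent to the joint objective; the combined form supports a literal
#' joint loop.
#'
#' @param l_roi temporal-stream reconstruction loss.
#' @param l_pcc connectivity-stream reconstruction loss.
#' @param lambda balancing coefficient, >= 0 (default 1).
#' @return scalar.
#' @export
joint_pretrain_loss <- function(l_roi, l_pcc, lambda = 1) {
  stopifnot(lambda >= 0)
  l_roi + lambda * l_pcc
}

#' Pre-train the connectivity encoder by masked element reconstruction
#'
#' Adam optimisation of the masked-element reconstruction objective over
#' per-subject flattened Pearson correlation vectors (computed once up
#' front). Padded patch positions never enter the loss.
#'
#' @param model a `tst2_model` (updated in place).
#' @param records list of [subject_record()] (correlation vectors are derived
#'   internally), or a list of numeric vectors.
#' @param epochs,batch_size,lr,weight_decay optimisation settings.
#' @param val_records optional validation records or vectors.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return data frame with per-epoch train (and validation) loss.
#' @export
pretrain_tst2 <- function(model, records, epochs = 100L, batch_size = 32L,
                          lr = 1e-4, weight_decay = 1e-4, val_records = NULL,
                          seed = 1L, verbose = FALSE) {
  as_vecs <- function(rs) {
    lapply(rs, function(r) {
      if (inherits(r, "subject_record")) {
        flatten_upper(compute_pcc(r$series))
      } else {
        as.numeric(r)
      }
    })
  }
  vecs <- as_vecs(records)
  val_vecs <- if (!is.null(val_records)) as_vecs(val_records)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  opt <- adam_init(model$params)
  n <- length(vecs)
  cfg <- model$cfg
  D <- model$D
  val_masks <- if (!is.null(val_vecs)) {
    lapply(seq_along(val_vecs), function(k) {
      sample_pcc_mask(D, cfg$m2, seed = seed * 1000L + k)
    })
  }
  # masked, non-pad positions in patch layout for a given index set
  mask_mat <- function(idx) {
    v <- rep(FALSE, D)
    v[idx] <- TRUE
    patchify(v, cfg$patch_len)$patches > 0
  }
  hist_tr <- numeric(epochs)
  hist_va <- rep(NA_real_, epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      ag_reset()
      total <- NULL
      for (s in idx) {
        p <- vecs[[s]]
        mi <- sample.int(D, max(1L, round(cfg$m2 * D)))
        out <- tst2_forward(model, p, mask_idx = mi, train = TRUE)
        ref <- patchify(p, cfg$patch_len)$patches
        l <- ag_mse_masked(out$phat_mat, ref, mask_mat(mi))
        total <- if (is.null(total)) l else ag_add(total, l)
      }
      total <- ag_scale(total, 1 / length(idx))
      ag_zero_grad(model$params)
      ag_backward(total)
      opt <- adam_step(model$params, opt, lr, weight_decay)
      ep_loss <- ep_loss + as.numeric(total$v); nb <- nb + 1L
    }
    hist_tr[ep] <- ep_loss / nb
    if (!is.null(val_vecs)) {
      vl <- 0
      for (k in seq_along(val_vecs)) {
        p <- val_vecs[[k]]
        ag_reset()
        out <- tst2_forward(model, p, mask_idx = val_masks[[k]])
        phat <- depatchify(out$phat_mat$v, D)
        vl <- vl + pcc_recon_loss(p, phat, val_masks[[k]])
      }
      hist_va[ep] <- vl / length(val_vecs)
    }
    if (verbose) {
      cat(sprintf("tst2 pretrain epoch %d train %.5f val %.5f\n",
                  ep, hist_tr[ep], hist_va[ep]))
    }
  }
  ag_reset()
  data.frame(epoch = seq_len(epochs), train_loss = hist_tr,
             val_loss = hist_va)
}
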