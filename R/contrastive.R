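#' Projection head configuration
#'
#' Each stream has its own projection head (their input dimensions differ),
#' with identical hidden and output sizes: a two-layer perceptron
#' `in -> hidden -> out` with a ReLU between, followed by L2 normalisation
#' onto the unit sphere.
#'
#' @param in_dim input feature dimension (`d1` or `d2`).
#' @param hidden hidden width.
#' @param out_dim contrastive embedding dimension.
#' @return a `proj_head_config`.
#' @export
proj_head_config <- function(in_dim, hidden = 256L, out_dim = 128L) {
  stopifnot(in_dim > 0, hidden > 0, out_dim > 0)
  structure(list(in_dim = as.integer(in_dim), hidden = as.integer(hidden),
                 out_dim = as.integer(out_dim)),
            class = "proj_head_config")
}

#' Initialise a projection head
#' @param cfg a [proj_head_config()].
#' @param seed integer seed.
#' @return a `proj_head` model.
#' @export
proj_head_init <- function(cfg, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  p <- new_mlp2(cfg$in_dim, cfg$hidden, cfg$out_dim, "proj.")
  structure(list(params = p, cfg = cfg), class = "proj_head")
}

proj_forward <- function(head, h) {
  ag_l2normalize_rows(mlp2_forward(head$params, "proj.", h))
}

#' Project a feature vector into the contrastive embedding space
#'
#' @param head a `proj_head`.
#' @param h numeric vector (or matrix of row vectors) of length `in_dim`.
#' @return unit-norm numeric vector (or matrix of unit rows).
#' @export
project <- function(head, h) {
  ag_reset()
  z <- proj_forward(head, ag_leaf(h))
  v <- z$v
  ag_reset()
  if (nrow(v) == 1L) as.numeric(v) else v
}

# log-sum-exp by row
lse_rows <- function(S) {
  mx <- apply(S, 1L, max)
  mx + log(rowSums(exp(S - mx)))
}

#' InfoNCE contrastive loss between paired embedding batches
#'
#' Temperature-scaled softmax classification of the matching pair among all
#' in-batch candidates: for anchor `z_t[i]`, the positive is `z_p[i]` and the
#' denominator runs over all N connectivity embeddings in the batch (positive
#' included). The default symmetrised form averages both retrieval directions
#' (temporal -> connectivity and the reverse); `direction = "t2p"` gives the
#' one-directional form.
#'
#' @param z_t N x m matrix of unit-norm temporal embeddings.
#' @param z_p N x m matrix of unit-norm connectivity embeddings.
#' @param tau temperature, > 0.
#' @param direction `"sym"` (default) or `"t2p"`.
#' @return scalar loss (non-negative; equals log N when all similarities are
#'   equal, and 0 when N = 1).
#' @export
infonce_loss <- function(z_t, z_p, tau = 0.07, direction = c("sym", "t2p")) {
  direction <- match.arg(direction)
  z_t <- as_row(z_t); z_p <- as_row(z_p)
  stopifnot(nrow(z_t) == nrow(z_p), tau > 0)
  N <- nrow(z_t)
  if (N == 0L) stop("empty batch")
  S <- z_t %*% t(z_p) / tau
  l_t2p <- mean(lse_rows(S) - diag(S))
  if (direction == "t2p") return(l_t2p)
  l_p2t <- mean(lse_rows(t(S)) - diag(S))
  (l_t2p + l_p2t) / 2
}

# tape version, identical semantics
infonce_node <- function(zt, zp, tau, direction = "sym") {
  N <- nrow(zt$v)
  S <- ag_scale(ag_matmul(zt, ag_t(zp)), 1 / tau)
  l1 <- ag_ce_logits(S, seq_len(N))
  if (direction == "t2p") return(l1)
  l2 <- ag_ce_logits(ag_t(S), seq_len(N))
  ag_scale(ag_add(l1, l2), 0.5)
}

#' Encoder freezing policy
#'
#' Which backbone encoders are updated during a training stage; the projection
#' heads are always trainable during contrastive alignment.
#'
#' @param policy one of `"both"` (freeze both encoders), `"tst1"`,
#'   `"tst2"` (freeze that encoder only) or `"none"` (unfreeze both).
#' @return a `freeze_policy` with logical fields `freeze_tst1`, `freeze_tst2`.
#' @export
freeze_policy <- function(policy = c("none", "both", "tst1", "tst2")) {
  policy <- match.arg(policy)
  structure(list(freeze_tst1 = policy %in% c("both", "tst1"),
                 freeze_tst2 = policy %in% c("both", "tst2"),
                 policy = policy),
            class = "freeze_policy")
}

# positive/negative mean cosine similarity and top-1 retrieval accuracy for
# paired unit embedding batches
alignment_stats <- function(Z1, Z2) {
  S <- Z1 %*% t(Z2)
  n <- nrow(S)
  pos <- mean(diag(S))
  neg <- if (n > 1L) (sum(S) - sum(diag(S))) / (n * (n - 1L)) else NA_real_
  top1 <- mean(max.col(S, ties.method = "first") == seq_len(n))
  c(pos_sim = pos, neg_sim = neg, top1 = top1)
}

#' Contrastive alignment of the two encoder streams
#'
#' Trains the two projection heads (and any unfrozen encoder) to minimise the
#' InfoNCE objective over subject-paired temporal/connectivity embeddings.
#' When both encoders are frozen their features are computed once and cached,
#' making the stage a light head-only optimisation.
#'
#' @param tst1,tst2 pre-trained encoder models (updated in place if unfrozen).
#' @param head1,head2 projection heads (always updated in place).
#' @param records training [subject_record()] list.
#' @param policy a [freeze_policy()].
#' @param epochs,batch_size,lr,weight_decay,tau optimisation settings
#'   (batch size must be at least 2: InfoNCE needs in-batch negatives).
#' @param direction InfoNCE direction, see [infonce_loss()].
#' @param val_records optional held-out records for the alignment report.
#' @param seed integer seed.
#' @param verbose print per-epoch statistics.
#' @return data frame per epoch: training loss, positive-pair mean cosine
#'   similarity, negative-pair mean, and in-batch top-1 retrieval accuracy on
#'   the report set (validation if given, else training).
#' @export
run_contrastive_stage <- function(tst1, tst2, head1, head2, records,
                                  policy = freeze_policy("none"),
                                  epochs = 50L, batch_size = 32L,
                                  lr = 1e-4, weight_decay = 1e-4,
                                  tau = 0.07, direction = "sym",
                                  val_records = NULL, seed = 1L,
                                  verbose = FALSE) {
  stopifnot(inherits(policy, "freeze_policy"))
  if (batch_size < 2L) stop("contrastive batch size must be >= 2 (no negatives otherwise)")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)

  n <- length(records)
  pcc_vecs <- lapply(records, function(r) flatten_upper(compute_pcc(r$series)))
  both_frozen <- policy$freeze_tst1 && policy$freeze_tst2

  H1 <- H2 <- NULL
  if (both_frozen) {
    H1 <- do.call(rbind, lapply(records, function(r) encode_roi(tst1, r$series)))
    H2 <- do.call(rbind, lapply(seq_len(n), function(k) encode_pcc(tst2, pcc_vecs[[k]])))
  }

  trainable <- c(head1$params, head2$params)
  if (!policy$freeze_tst1) trainable <- c(trainable, tst1$params)
  if (!policy$freeze_tst2) trainable <- c(trainable, tst2$params)
  opt <- adam_init(trainable)

  report_embeddings <- function() {
    rr <- if (!is.null(val_records)) val_records else records
    Z1 <- do.call(rbind, lapply(rr, function(r) project(head1, encode_roi(tst1, r$series))))
    Z2 <- do.call(rbind, lapply(rr, function(r) {
      project(head2, encode_pcc(tst2, flatten_upper(compute_pcc(r$series))))
    }))
    list(Z1 = Z1, Z2 = Z2)
  }

  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                     pos_sim = NA_real_, neg_sim = NA_real_, top1 = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next
      ag_reset()
      if (both_frozen) {
        h1b <- ag_leaf(H1[idx, , drop = FALSE])
        h2b <- ag_leaf(H2[idx, , drop = FALSE])
      } else {
        h1l <- lapply(idx, function(s) {
          if (policy$freeze_tst1) {
            ag_leaf(matrix(encode_tape_free(tst1, records[[s]]$series), nrow = 1L))
          } else {
            tst1_forward(tst1, records[[s]]$series)$h
          }
        })
        h2l <- lapply(idx, function(s) {
          if (policy$freeze_tst2) {
            ag_leaf(matrix(encode_pcc_tape_free(tst2, pcc_vecs[[s]]), nrow = 1L))
          } else {
            tst2_forward(tst2, pcc_vecs[[s]])$h
          }
        })
        h1b <- ag_vstack(h1l)
        h2b <- ag_vstack(h2l)
      }
      z1 <- proj_forward(head1, h1b)
      z2 <- proj_forward(head2, h2b)
      loss <- infonce_node(z1, z2, tau, direction)
      ag_zero_grad(trainable)
      ag_backward(loss)
      opt <- adam_step(trainable, opt, lr, weight_decay)
      ep_loss <- ep_loss + as.numeric(loss$v); nb <- nb + 1L
    }
    st <- {
      Z <- report_embeddings()
      alignment_stats(Z$Z1, Z$Z2)
    }
    hist$loss[ep] <- ep_loss / max(nb, 1L)
    hist$pos_sim[ep] <- st["pos_sim"]
    hist$neg_sim[ep] <- st["neg_sim"]
    hist$top1[ep] <- st["top1"]
    if (verbose) {
      cat(sprintf("contrastive epoch %d loss %.4f pos %.3f neg %.3f top1 %.2f\n",
                  ep, hist$loss[ep], hist$pos_sim[ep], hist$neg_sim[ep],
                  hist$top1[ep]))
    }
  }
  ag_reset()
  hist
}

# frozen-encoder forward passes that do not pollute the active tape: run the
# encoder on a scratch tape and return plain values
encode_tape_free <- function(tst1, series) {
  saved <- list(tape = .ag$tape, n = .ag$n)
  ag_reset()
  v <- as.numeric(tst1_forward(tst1, series)$h$v)
  .ag$tape <- saved$tape; .ag$n <- saved$n
  v
}

encode_pcc_tape_free <- function(tst2, vec) {
  saved <- list(tape = .ag$tape, n = .ag$n)
  ag_reset()
  v <- as.numeric(tst2_forward(tst2, vec)$h$v)
  .ag$tape <- saved$tape; .ag$n <- saved$n
  v
}
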