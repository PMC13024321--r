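#' Configuration of the temporal-stream encoder
#'
#' The temporal encoder is an encoder-only transformer over the raw ROI time
#' series. Each time point (a length-R vector of ROI values) is linearly
#' projected to `d1` dimensions, sinusoidal positional encodings are added, a
#' learnable [CLS] token is prepended, and `L1` encoder layers are applied;
#' the subject representation is the final [CLS] embedding. Pre-training masks
#' whole time points and reconstructs them.
#'
#' @param d1 embedding dimension (must be divisible by `heads`).
#' @param L1 number of encoder layers.
#' @param heads attention heads.
#' @param ff_dim feed-forward hidden dimension.
#' @param dropout dropout rate used during training.
#' @param mask_ratio_range range (low, high) from which the masking ratio is
#'   drawn uniformly at each pre-training step.
#' @param mask_input how masked time points are represented before the input
#'   projection: a learned mask-token embedding (`"token"`, default) or zeros
#'   (`"zero"`).
#' @return a `tst1_config` list.
#' @export
tst1_config <- function(d1 = 512L, L1 = 6L, heads = 8L, ff_dim = 2048L,
                        dropout = 0.1, mask_ratio_range = c(0.25, 0.5),
                        mask_input = c("token", "zero")) {
  mask_input <- match.arg(mask_input)
  stopifnot(d1 %% heads == 0,
            length(mask_ratio_range) == 2,
            mask_ratio_range[1] > 0,
            mask_ratio_range[1] <= mask_ratio_range[2],
            mask_ratio_range[2] < 1)
  structure(list(d1 = as.integer(d1), L1 = as.integer(L1),
                 heads = as.integer(heads), ff_dim = as.integer(ff_dim),
                 dropout = dropout, mask_ratio_range = mask_ratio_range,
                 mask_input = mask_input),
            class = "tst1_config")
}

#' Initialise a temporal-stream encoder
#'
#' @param R number of ROI columns the encoder accepts.
#' @param cfg a [tst1_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `tst1_model` (parameters are mutable environments; training
#'   updates them in place).
#' @export
tst1_init <- function(R, cfg = tst1_config(), seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  p <- list()
  lin <- init_linear(R, cfg$d1)
  p[["in.W"]] <- lin$W
  p[["in.b"]] <- lin$b
  p[["cls"]] <- ag_leaf(matrix(stats::rnorm(cfg$d1, sd = 0.02), 1, cfg$d1))
  p[["mask_tok"]] <- ag_leaf(matrix(stats::rnorm(R, sd = 0.02), 1, R))
  for (l in seq_len(cfg$L1)) {
    p <- c(p, new_tf_layer(cfg$d1, cfg$ff_dim, sprintf("l%d.", l)))
  }
  dec <- init_linear(cfg$d1, R)
  p[["dec.W"]] <- dec$W
  p[["dec.b"]] <- dec$b
  structure(list(params = p, cfg = cfg, R = as.integer(R)),
            class = "tst1_model")
}

# Forward pass on the autodiff tape. `x` is a T x R numeric matrix or an
# agnode leaf (the latter used for input-gradient attribution). `mask_rows`
# marks time points whose content is replaced by the mask representation.
tst1_forward <- function(model, x, mask_rows = NULL, train = FALSE) {
  cfg <- model$cfg
  prm <- model$params
  xn <- if (is_agnode(x)) x else ag_leaf(x)
  T_len <- nrow(xn$v)
  if (ncol(xn$v) != model$R) {
    stop("series has ", ncol(xn$v), " ROI columns; encoder expects ", model$R)
  }
  if (!is.null(mask_rows)) {
    if (any(mask_rows < 1L) || any(mask_rows > T_len)) {
      stop("mask indices out of range")
    }
    keep <- matrix(1, T_len, 1L)
    keep[mask_rows, 1L] <- 0
    xn <- ag_mul(xn, ag_leaf(matrix(rep(keep, model$R), T_len)))
    if (cfg$mask_input == "token") {
      ind <- matrix(0, T_len, 1L)
      ind[mask_rows, 1L] <- 1
      xn <- ag_add(xn, ag_matmul(ag_leaf(ind), prm[["mask_tok"]]))
    }
  }
  z <- ag_add(ag_matmul(xn, prm[["in.W"]]), prm[["in.b"]])
  tokens <- ag_vstack(list(prm[["cls"]], z))
  tokens <- ag_add(tokens, ag_leaf(sinusoidal_pe(T_len + 1L, cfg$d1)))
  if (train && cfg$dropout > 0) tokens <- ag_dropout(tokens, cfg$dropout)
  for (l in seq_len(cfg$L1)) {
    tokens <- tf_layer_forward(prm, sprintf("l%d.", l), tokens, cfg$heads,
                               cfg$dropout, train)
  }
  h <- ag_rows(tokens, 1L)
  xhat <- ag_add(ag_matmul(ag_rows(tokens, 2L:(T_len + 1L)), prm[["dec.W"]]),
                 prm[["dec.b"]])
  list(h = h, xhat = xhat)
}

#' Encode an ROI time series into the temporal-stream representation
#'
#' Runs the encoder in evaluation mode (no dropout, deterministic) and returns
#' the [CLS]-token embedding.
#'
#' @param model a `tst1_model`.
#' @param series T x R numeric matrix; T may differ between calls (positional
#'   encodings extend analytically).
#' @return numeric vector of length `d1`.
#' @export
encode_roi <- function(model, series) {
  ag_reset()
  out <- tst1_forward(model, as.matrix(series), train = FALSE)
  v <- as.numeric(out$h$v)
  ag_reset()
  v
}

#' Sample a time-point mask for reconstruction pre-training
#'
#' The masking ratio is drawn uniformly from the configured range, then
#' `round(ratio * T)` distinct time points are sampled without replacement.
#'
#' @param T_len number of time points (>= 4).
#' @param cfg a [tst1_config()].
#' @param seed integer seed; the mask is deterministic given the seed.
#' @return a `mask_spec`: list with `masked_rows` (sorted 1-based indices),
#'   `ratio` and `seed`.
#' @export
sample_mask <- function(T_len, cfg = tst1_config(), seed = 1L) {
  stopifnot(T_len >= 4L)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  lo <- cfg$mask_ratio_range[1]; hi <- cfg$mask_ratio_range[2]
  ratio <- if (lo == hi) lo else stats::runif(1L, lo, hi)
  k <- max(1L, round(ratio * T_len))
  structure(list(masked_rows = sort(sample.int(T_len, k)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "mask_spec")
}

#' Reconstruct a masked ROI series
#'
#' Replaces the masked time points by the learned mask representation, runs
#' the encoder and the linear reconstruction head, and returns the full
#' reconstructed matrix (only masked positions enter the pre-training loss).
#'
#' @param model a `tst1_model`.
#' @param series T x R numeric matrix.
#' @param mask a `mask_spec` from [sample_mask()].
#' @return T x R reconstruction.
#' @export
reconstruct_roi <- function(model, series, mask) {
  ag_reset()
  out <- tst1_forward(model, as.matrix(series), mask_rows = mask$masked_rows)
  v <- out$xhat$v
  ag_reset()
  v
}

#' Masked reconstruction loss for the temporal stream
#'
#' Mean squared error over the masked entries only: the mask covers whole
#' time-point rows, so the loss averages over `|masked rows| * R` entries.
#'
#' @param x original T x R matrix.
#' @param x_hat reconstructed T x R matrix.
#' @param mask a `mask_spec` (or integer vector of masked row indices).
#' @return scalar loss.
#' @export
roi_recon_loss <- function(x, x_hat, mask) {
  rows <- if (inherits(mask, "mask_spec")) mask$masked_rows else as.integer(mask)
  if (length(rows) == 0L) stop("empty mask")
  stopifnot(identical(dim(as.matrix(x)), dim(as.matrix(x_hat))),
            all(rows >= 1L), all(rows <= nrow(x)))
  d <- (as.matrix(x) - as.matrix(x_hat))[rows, , drop = FALSE]
  mean(d * d)
}

#' Pre-train the temporal encoder by masked reconstruction
#'
#' Adam optimisation of the masked time-point reconstruction objective. The
#' masking ratio is re-drawn per batch from the configured range. Validation
#' loss, when a validation set is supplied, is computed with fixed per-subject
#' masks (drawn once) so epochs are comparable.
#'
#' @param model a `tst1_model` (updated in place).
#' @param records list of [subject_record()].
#' @param epochs,batch_size,lr,weight_decay optimisation settings.
#' @param val_records optional validation records.
#' @param seed integer seed for masking and batch order.
#' @param verbose print per-epoch losses.
#' @return data frame with per-epoch train (and validation) reconstruction
#'   loss.
#' @export
pretrain_tst1 <- function(model, records, epochs = 100L, batch_size = 32L,
                          lr = 1e-4, weight_decay = 1e-4, val_records = NULL,
                          seed = 1L, verbose = FALSE) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  opt <- adam_init(model$params)
  n <- length(records)
  val_masks <- NULL
  if (!is.null(val_records)) {
    val_masks <- lapply(seq_along(val_records), function(k) {
      sample_mask(nrow(val_records[[k]]$series), model$cfg,
                  seed = seed * 1000L + k)
    })
  }
  hist_tr <- numeric(epochs)
  hist_va <- rep(NA_real_, epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      ag_reset()
      ratio <- stats::runif(1L, model$cfg$mask_ratio_range[1],
                            model$cfg$mask_ratio_range[2])
      total <- NULL
      for (s in idx) {
        X <- records[[s]]$series
        T_len <- nrow(X)
        k <- max(1L, round(ratio * T_len))
        rows <- sample.int(T_len, k)
        out <- tst1_forward(model, X, mask_rows = rows, train = TRUE)
        mm <- matrix(FALSE, T_len, ncol(X)); mm[rows, ] <- TRUE
        l <- ag_mse_masked(out$xhat, X, mm)
        total <- if (is.null(total)) l else ag_add(total, l)
      }
      total <- ag_scale(total, 1 / length(idx))
      ag_zero_grad(model$params)
      ag_backward(total)
      opt <- adam_step(model$params, opt, lr, weight_decay)
      ep_loss <- ep_loss + as.numeric(total$v); nb <- nb + 1L
    }
    hist_tr[ep] <- ep_loss / nb
    if (!is.null(val_records)) {
      vl <- 0
      for (k in seq_along(val_records)) {
        X <- val_records[[k]]$series
        xh <- reconstruct_roi(model, X, val_masks[[k]])
        vl <- vl + roi_recon_loss(X, xh, val_masks[[k]])
      }
      hist_va[ep] <- vl / length(val_records)
    }
    if (verbose) {
      cat(sprintf("tst1 pretrain epoch %d train %.5f val %.5f\n",
                  ep, hist_tr[ep], hist_va[ep]))
    }
  }
  ag_reset()
  data.frame(epoch = seq_len(epochs), train_loss = hist_tr,
             val_loss = hist_va)
}
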