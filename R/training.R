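#' Fine-tuning configuration
#'
#' @param epochs maximum fine-tuning epochs.
#' @param patience early-stopping patience: training stops once the validation
#'   AUC has not improved for this many consecutive epochs, and the
#'   best-validation-AUC parameters are restored (AUC, not loss, is the model
#'   selection metric).
#' @param lr,weight_decay,batch_size Adam settings.
#' @param freeze a [freeze_policy()] for the encoders during fine-tuning.
#'   The default leaves both encoders unfrozen, the configuration that
#'   performs best empirically; `"both"` gives the light-weight variant where
#'   only heads, fusion and classifier are trained.
#' @param freeze_proj_heads keep the contrastive projection heads fixed.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 100L, patience = 20L, lr = 5e-5,
                         weight_decay = 1e-4, batch_size = 32L,
                         freeze = freeze_policy("none"),
                         freeze_proj_heads = FALSE) {
  stopifnot(epochs >= 1, patience >= 1, patience <= epochs, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), freeze = freeze,
                 freeze_proj_heads = freeze_proj_heads),
            class = "train_config")
}

#' Classification metrics at a decision threshold
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with average ranks
#' for ties; accuracy, sensitivity (true positive rate), specificity (true
#' negative rate) and F1 are computed from the confusion matrix at the stated
#' threshold (scores at or above the threshold predict the positive class).
#'
#' @param labels binary vector (1 = positive/ASD).
#' @param scores predicted positive-class probabilities.
#' @param threshold decision threshold, default 0.5.
#' @return list with `auc`, `acc`, `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(auc = auc,
       acc = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Fine-tune a dual-stream model for classification
#'
#' Supervised cross-entropy training of the fusion module and classifier,
#' together with the projection heads and any unfrozen encoder, with early
#' stopping on validation AUC. The parameters achieving the best validation
#' AUC are restored before the function returns, and training never continues
#' more than `patience` epochs past that best epoch.
#'
#' @param model a [ds_model()] (updated in place).
#' @param train_records,val_records training and validation subjects; the
#'   validation split must be non-empty and contain both classes.
#' @param cfg a [train_config()].
#' @param seed integer seed (batch order, dropout).
#' @return list with `history` (per-epoch train loss and validation AUC),
#'   `best_val_auc` and `best_epoch`.
#' @export
finetune <- function(model, train_records, val_records,
                     cfg = train_config(), seed = 1L) {
  if (length(val_records) == 0L) stop("empty validation split")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)

  n <- length(train_records)
  labels <- vapply(train_records, `[[`, 0L, "label")
  trainable <- model_trainables(model, cfg$freeze, cfg$freeze_proj_heads)
  opt <- adam_init(trainable)

  need_p <- model$backbone != "tst1"
  need_x <- model$backbone != "tst2"
  pvecs <- if (need_p) {
    lapply(train_records, function(r) flatten_upper(compute_pcc(r$series)))
  }
  # frozen encoders: cache their features once
  c1 <- need_x && cfg$freeze$freeze_tst1
  c2 <- need_p && cfg$freeze$freeze_tst2
  H1 <- if (c1) do.call(rbind, lapply(train_records,
                                      function(r) encode_roi(model$tst1, r$series)))
  H2 <- if (c2) do.call(rbind, lapply(seq_len(n),
                                      function(k) encode_pcc(model$tst2, pvecs[[k]])))
  # when every needed encoder is frozen, validation features are also fixed:
  # cache them so per-epoch model selection only re-runs heads and fusion
  all_frozen <- (!need_x || c1) && (!need_p || c2)
  V1 <- V2 <- NULL
  if (all_frozen) {
    if (need_x) V1 <- do.call(rbind, lapply(val_records,
                                            function(r) encode_roi(model$tst1, r$series)))
    if (need_p) V2 <- do.call(rbind, lapply(val_records, function(r) {
      encode_pcc(model$tst2, flatten_upper(compute_pcc(r$series)))
    }))
  }

  batch_logits <- function(idx, train) {
    f1 <- f2 <- NULL
    if (need_x) {
      h1 <- if (c1) ag_leaf(H1[idx, , drop = FALSE]) else {
        ag_vstack(lapply(idx, function(s) {
          tst1_forward(model$tst1, train_records[[s]]$series, train = train)$h
        }))
      }
      f1 <- if (model$use_heads) proj_forward(model$head1, h1) else h1
    }
    if (need_p) {
      h2 <- if (c2) ag_leaf(H2[idx, , drop = FALSE]) else {
        ag_vstack(lapply(idx, function(s) {
          tst2_forward(model$tst2, pvecs[[s]], train = train)$h
        }))
      }
      f2 <- if (model$use_heads) proj_forward(model$head2, h2) else h2
    }
    fu <- if (model$backbone == "dual") {
      fuse_forward(model$fusion, f1, f2)
    } else {
      fuse_forward(model$fusion, if (model$backbone == "tst1") f1 else f2, NULL)
    }
    classifier_forward(model$fusion, fu$fused, train = train)
  }

  val_scores_cached <- function() {
    ag_reset()
    f1 <- f2 <- NULL
    if (need_x) {
      h1 <- ag_leaf(V1)
      f1 <- if (model$use_heads) proj_forward(model$head1, h1) else h1
    }
    if (need_p) {
      h2 <- ag_leaf(V2)
      f2 <- if (model$use_heads) proj_forward(model$head2, h2) else h2
    }
    fu <- if (model$backbone == "dual") {
      fuse_forward(model$fusion, f1, f2)
    } else {
      fuse_forward(model$fusion, if (model$backbone == "tst1") f1 else f2, NULL)
    }
    lv <- classifier_forward(model$fusion, fu$fused, train = FALSE)$v
    ag_reset()
    e <- exp(lv - apply(lv, 1L, max))
    (e / rowSums(e))[, 2L]
  }

  best_auc <- -Inf; best_epoch <- 0L; best_snap <- NULL
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_auc = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      ag_reset()
      logits <- batch_logits(idx, train = TRUE)
      loss <- ag_ce_logits(logits, labels[idx] + 1L)
      ag_zero_grad(trainable)
      ag_backward(loss)
      opt <- adam_step(trainable, opt, cfg$lr, cfg$weight_decay)
      ep_loss <- ep_loss + as.numeric(loss$v); nb <- nb + 1L
    }
    val_scores <- if (all_frozen) val_scores_cached()
                  else predict_scores(model, val_records)
    val_auc <- compute_metrics(vapply(val_records, `[[`, 0L, "label"),
                               val_scores)$auc
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_auc = val_auc))
    if (val_auc > best_auc) {
      best_auc <- val_auc; best_epoch <- ep
      best_snap <- params_snapshot(trainable)
    } else if (ep - best_epoch >= cfg$patience) {
      break
    }
  }
  if (!is.null(best_snap)) params_restore(trainable, best_snap)
  ag_reset()
  list(history = hist, best_val_auc = best_auc, best_epoch = best_epoch)
}

#' Mean relative parameter change of a module
#'
#' For each parameter tensor the Frobenius norm of the update is divided by
#' the Frobenius norm of the starting value (epsilon-guarded), and the ratios
#' are averaged over tensors. An unchanged module scores exactly 0; doubling
#' every (non-zero) tensor scores exactly 1.
#'
#' @param before,after matching parameter snapshots: named lists of numeric
#'   matrices (as returned by taking the module's parameter values before and
#'   after a training stage), or models with a `params` field.
#' @return scalar mean relative change.
#' @export
relative_parameter_change <- function(before, after) {
  get_vals <- function(x) {
    if (is.list(x) && !is.null(x$params)) {
      lapply(x$params, function(p) p$v)
    } else if (is.list(x) && all(vapply(x, is_agnode, TRUE))) {
      lapply(x, function(p) p$v)
    } else {
      x
    }
  }
  b <- get_vals(before); a <- get_vals(after)
  if (length(b) != length(a)) stop("parameter structure mismatch")
  if (!is.null(names(b)) && !is.null(names(a)) && !identical(names(b), names(a))) {
    stop("parameter structure mismatch: names differ")
  }
  ratios <- vapply(seq_along(b), function(k) {
    if (!identical(dim(as.matrix(b[[k]])), dim(as.matrix(a[[k]])))) {
      stop("parameter structure mismatch: tensor ", k, " shape differs")
    }
    num <- sqrt(sum((a[[k]] - b[[k]])^2))
    den <- sqrt(sum(b[[k]]^2)) + 1e-12
    num / den
  }, 0)
  mean(ratios)
}

#' Multi-seed comparison of configurations with paired t-tests
#'
#' Performs a paired two-tailed t-test for every pair of configurations over
#' matched seeds and applies a Bonferroni correction across the comparisons.
#' Identical vectors are reported as "no difference" (p = 1); a constant
#' non-zero difference (zero variance of the paired differences) is flagged as
#' degenerate with p reported as 0.
#'
#' @param runs named list of equal-length numeric vectors (per-seed metric
#'   values, e.g. AUC, one vector per configuration; at least 2 seeds).
#' @return data frame with one row per comparison: means, mean difference,
#'   raw and Bonferroni-adjusted p-values, significance stars
#'   (0.05 / 0.01 / 0.001) and a note for degenerate cases.
#' @export
compare_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 2, !is.null(names(runs)))
  lens <- vapply(runs, length, 1L)
  if (length(unique(lens)) != 1L) stop("equal seed counts required")
  if (lens[1] < 2L) stop("at least 2 seeds required")
  combs <- utils::combn(names(runs), 2L)
  n_comp <- ncol(combs)
  out <- lapply(seq_len(n_comp), function(k) {
    a <- runs[[combs[1, k]]]; b <- runs[[combs[2, k]]]
    d <- a - b
    note <- ""
    if (all(d == 0)) {
      p <- 1; tt <- NA_real_; note <- "identical vectors; no difference"
    } else if (stats::sd(d) == 0) {
      p <- 0; tt <- Inf * sign(mean(d))
      note <- "degenerate: constant non-zero difference (sd = 0)"
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      p <- ht$p.value; tt <- unname(ht$statistic)
    }
    p_adj <- min(1, p * n_comp)
    stars <- if (p_adj < 0.001) "***" else if (p_adj < 0.01) "**"
             else if (p_adj < 0.05) "*" else ""
    data.frame(config_a = combs[1, k], config_b = combs[2, k],
               mean_a = mean(a), mean_b = mean(b), diff = mean(d),
               t = tt, p = p, p_adj = p_adj, signif = stars, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sliding-window starts for a series of length T_len
window_starts <- function(T_len, window_len, window_stride) {
  if (is.null(window_len) || window_len >= T_len) return(1L)
  stride <- if (is.null(window_stride)) window_len else window_stride
  st <- seq.int(1L, T_len - window_len + 1L, by = stride)
  st
}

#' Leave-one-site-out cross-validation
#'
#' For every site, a model is trained on all other sites (by the supplied
#' factory) and evaluated on the held-out site. Subject-level predictions
#' aggregate sliding-window predictions by majority vote (ties broken toward
#' the positive class); the subject-level score used for AUC is the mean
#' window probability. The default window is the full series (one window per
#' subject), in which case voting reduces bit-exactly to plain evaluation.
#'
#' @param records list of [subject_record()] spanning at least 2 sites.
#' @param factory function(train_records, seed) returning a fitted
#'   [ds_model()] — it owns its internal train/validation split.
#' @param seed integer seed passed to the factory per fold.
#' @param window_len,window_stride optional sliding-window length and stride
#'   (time points).
#' @param threshold window-level decision threshold.
#' @return list with `table` (one row per site: n, class counts and metrics;
#'   AUC is NA when the held-out site has a single class) and `folds`
#'   (per-site subject ids, votes, scores and the train/test partition).
#' @export
loso_evaluate <- function(records, factory, seed = 1L, window_len = NULL,
                          window_stride = NULL, threshold = 0.5) {
  sites <- vapply(records, `[[`, "", "site")
  usites <- sort(unique(sites))
  if (length(usites) < 2L) stop("need at least 2 sites for LOSO")
  rows <- list(); folds <- list()
  for (s in usites) {
    test_idx <- which(sites == s)
    train_idx <- which(sites != s)
    if (length(test_idx) < 1L) {
      warning("site ", s, " has no subjects; skipped")
      next
    }
    model <- factory(records[train_idx], seed)
    test_recs <- records[test_idx]
    scores <- numeric(length(test_recs))
    votes <- integer(length(test_recs))
    for (k in seq_along(test_recs)) {
      X <- test_recs[[k]]$series
      st <- window_starts(nrow(X), window_len, window_stride)
      wl <- if (is.null(window_len)) nrow(X) else min(window_len, nrow(X))
      wrecs <- lapply(st, function(a) {
        r <- test_recs[[k]]
        r$series <- X[a:(a + wl - 1L), , drop = FALSE]
        r
      })
      wp <- predict_scores(model, wrecs)
      scores[k] <- mean(wp)
      n_pos <- sum(wp >= threshold)
      votes[k] <- as.integer(n_pos >= length(wp) - n_pos)  # ties -> positive
    }
    lab <- vapply(test_recs, `[[`, 0L, "label")
    tp <- sum(votes == 1L & lab == 1L); tn <- sum(votes == 0L & lab == 0L)
    fp <- sum(votes == 1L & lab == 0L); fn <- sum(votes == 0L & lab == 1L)
    auc <- if (length(unique(lab)) == 2L) {
      compute_metrics(lab, scores, threshold)$auc
    } else NA_real_
    rows[[s]] <- data.frame(
      site = s, n = length(lab), n_asd = sum(lab == 1L), n_td = sum(lab == 0L),
      auc = auc, acc = (tp + tn) / length(lab),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
      stringsAsFactors = FALSE)
    folds[[s]] <- list(
      test_ids = vapply(test_recs, `[[`, "", "subject_id"),
      train_ids = vapply(records[train_idx], `[[`, "", "subject_id"),
      votes = votes, scores = scores, labels = lab)
  }
  list(table = do.call(rbind, rows), folds = folds)
}
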