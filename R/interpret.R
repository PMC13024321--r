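#' ASD logit of a model as a differentiable node
#'
#' Generic hook used by the gradient-attribution functions: given autodiff
#' leaf nodes for a subject's time series (`x`, T x R) and/or connectivity
#' vector (`p`, 1 x D), return the positive-class (ASD) logit as a scalar
#' node. The method for [ds_model()] runs the full evaluation-mode forward
#' pass; other classes (e.g. analytic surrogates in tests) can supply their
#' own differentiable forward.
#'
#' @param model the model.
#' @param x agnode leaf for the series, or NULL.
#' @param p agnode leaf for the connectivity vector, or NULL.
#' @return a 1 x 1 autodiff node.
#' @export
asd_logit <- function(model, x = NULL, p = NULL) UseMethod("asd_logit")

#' @export
asd_logit.ds_model <- function(model, x = NULL, p = NULL) {
  fw <- model_forward_one(model, x = x, p = p, train = FALSE)
  ag_get(fw$logits, 1L, 2L)
}

# one backward pass per sample; returns per-sample input gradients
input_gradients <- function(model, samples) {
  if (length(samples) == 0L) stop("empty sample list")
  lapply(samples, function(rec) {
    ag_reset()
    X <- rec$series
    xn <- ag_leaf(X)
    # a sample may carry a pre-computed (or externally supplied) connectivity
    # vector; otherwise it is derived from the series
    pv <- if (!is.null(rec$pcc_vec)) rec$pcc_vec
          else flatten_upper(compute_pcc(X))
    pn <- ag_leaf(matrix(pv, nrow = 1L))
    logit <- asd_logit(model, x = xn, p = pn)
    ag_backward(logit)
    gx <- if (is.null(xn$g)) matrix(0, nrow(X), ncol(X)) else xn$g
    gp <- if (is.null(pn$g)) numeric(ncol(pn$v)) else as.numeric(pn$g)
    ag_reset()
    list(gx = gx, gp = gp)
  })
}

#' Gradient-based connection importance
#'
#' For each subject, the gradient of the ASD logit with respect to every
#' flattened Pearson-correlation entry is computed through the connectivity
#' stream (the correlation vector is treated as the independent variable: its
#' dependence on the time series is not chained). Absolute values are averaged
#' over subjects and scattered back onto a symmetric R x R matrix with a zero
#' diagonal via the package's fixed row-major edge ordering.
#'
#' @param model a [ds_model()] (or any class with an [asd_logit()] method
#'   differentiable in `p`).
#' @param samples list of [subject_record()] to average over (typically the
#'   held-out test split).
#' @return non-negative symmetric R x R matrix, zero diagonal.
#' @export
connection_importance <- function(model, samples) {
  grads <- input_gradients(model, samples)
  gp <- Reduce(`+`, lapply(grads, function(g) abs(g$gp))) / length(grads)
  D <- length(gp)
  R <- as.integer(round((1 + sqrt(1 + 8 * D)) / 2))
  conn <- matrix(0, R, R)
  pr <- upper_pairs(R)
  conn[pr] <- gp
  conn[pr[, c(2, 1)]] <- gp
  conn
}

#' Gradient-based ROI importance
#'
#' For each subject, the gradients of the ASD logit with respect to the raw
#' time series are aggregated over the temporal dimension first (signed mean
#' over time points), the absolute value of the aggregate is taken, and the
#' result is averaged over subjects. Set `abs_first = TRUE` for the
#' alternative reading that takes absolute values before the temporal mean
#' (which cannot cancel opposing temporal contributions).
#'
#' @param model a [ds_model()] (or any class with an [asd_logit()] method
#'   differentiable in `x`).
#' @param samples list of [subject_record()].
#' @param abs_first take absolute values before the temporal aggregation.
#' @return non-negative numeric vector of length R.
#' @export
roi_importance <- function(model, samples, abs_first = FALSE) {
  grads <- input_gradients(model, samples)
  per_sample <- lapply(grads, function(g) {
    if (abs_first) colMeans(abs(g$gx)) else abs(colMeans(g$gx))
  })
  Reduce(`+`, per_sample) / length(per_sample)
}

#' Top-ranked connections of an importance matrix
#'
#' @param conn symmetric R x R importance matrix.
#' @param k number of connections to return; values above R(R-1)/2 are
#'   clipped with a warning.
#' @return data frame (i, j, score) of the k largest strict-upper-triangle
#'   entries, descending; ties broken by (i, j) lexicographic order.
#' @export
top_connections <- function(conn, k) {
  conn <- as.matrix(conn)
  R <- nrow(conn)
  stopifnot(ncol(conn) == R, k >= 0)
  pr <- upper_pairs(R)
  sc <- conn[pr]
  D <- nrow(pr)
  if (k > D) {
    warning("k = ", k, " exceeds the number of connections (", D, "); clipped")
    k <- D
  }
  ord <- order(-sc, pr[, 1], pr[, 2])
  out <- data.frame(i = pr[ord, 1], j = pr[ord, 2], score = sc[ord])
  out[seq_len(k), , drop = FALSE]
}

#' Full importance report
#'
#' Convenience wrapper computing both attribution maps and the top
#' connections in one pass over the samples.
#'
#' @param model a [ds_model()].
#' @param samples list of [subject_record()].
#' @param k number of top connections to tabulate.
#' @return an `importance_report`: list with `conn` (R x R), `roi` (length R),
#'   `top_connections` (data frame) and `n_samples_averaged`.
#' @export
importance_report <- function(model, samples, k = 20L) {
  grads <- input_gradients(model, samples)
  gp <- Reduce(`+`, lapply(grads, function(g) abs(g$gp))) / length(grads)
  D <- length(gp)
  R <- as.integer(round((1 + sqrt(1 + 8 * D)) / 2))
  conn <- matrix(0, R, R)
  pr <- upper_pairs(R)
  conn[pr] <- gp
  conn[pr[, c(2, 1)]] <- gp
  roi <- Reduce(`+`, lapply(grads, function(g) abs(colMeans(g$gx)))) /
    length(grads)
  structure(list(conn = conn, roi = roi,
                 top_connections = top_connections(conn, min(k, nrow(pr))),
                 n_samples_averaged = length(samples)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report: %d ROIs, averaged over %d samples>\n",
              length(x$roi), x$n_samples_averaged))
  cat("top connections:\n")
  print(utils::head(x$top_connections, 5L))
  invisible(x)
}
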