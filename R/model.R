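#' Assemble a dual-stream classification model
#'
#' Bundles the two pre-trained encoders, the (optional) contrastive
#' projection heads and the fusion + classifier module into a single model.
#' When the projection heads are used, fine-tuning and prediction route each
#' stream's feature through its head before fusion (the contrastive embedding
#' is the fusion input); without heads the raw encoder features feed the
#' fusion directly.
#'
#' @param tst1 a `tst1_model` (or NULL for a connectivity-only model).
#' @param tst2 a `tst2_model` (or NULL for a temporal-only model).
#' @param head1,head2 `proj_head`s or NULL.
#' @param fusion a `fusion_model`; its input dimensions must match the stream
#'   feature dimensions implied by `use_heads`.
#' @param use_heads route features through the projection heads.
#' @param backbone `"dual"`, `"tst1"` (temporal only) or `"tst2"`
#'   (connectivity only); single-backbone models feed the lone (projected)
#'   feature straight to the classifier.
#' @return a `ds_model`.
#' @export
ds_model <- function(tst1, tst2, head1 = NULL, head2 = NULL, fusion,
                     use_heads = !is.null(head1),
                     backbone = c("dual", "tst1", "tst2")) {
  backbone <- match.arg(backbone)
  if (backbone %in% c("dual", "tst1")) stopifnot(!is.null(tst1))
  if (backbone %in% c("dual", "tst2")) stopifnot(!is.null(tst2))
  if (use_heads) {
    if (backbone != "tst2") stopifnot(!is.null(head1))
    if (backbone != "tst1") stopifnot(!is.null(head2))
  }
  structure(list(tst1 = tst1, tst2 = tst2, head1 = head1, head2 = head2,
                 fusion = fusion, use_heads = use_heads, backbone = backbone),
            class = "ds_model")
}

#' @export
print.ds_model <- function(x, ...) {
  cat(sprintf("<ds_model backbone=%s fusion=%s heads=%s>\n", x$backbone,
              x$fusion$cfg$method, if (x$use_heads) "yes" else "no"))
  invisible(x)
}

# Tape forward of the full model for ONE subject. `x` (T x R matrix or node)
# and/or `p` (length-D vector or 1 x D node) depending on the backbone.
# Returns list(logits (1 x 2 node), fused).
model_forward_one <- function(model, x = NULL, p = NULL, train = FALSE) {
  f1 <- f2 <- NULL
  if (model$backbone != "tst2") {
    h1 <- tst1_forward(model$tst1, x, train = train)$h
    f1 <- if (model$use_heads) proj_forward(model$head1, h1) else h1
  }
  if (model$backbone != "tst1") {
    h2 <- tst2_forward(model$tst2, p, train = train)$h
    f2 <- if (model$use_heads) proj_forward(model$head2, h2) else h2
  }
  if (model$backbone == "dual") {
    fu <- fuse_forward(model$fusion, f1, f2)
  } else {
    lone <- if (model$backbone == "tst1") f1 else f2
    fu <- fuse_forward(model$fusion, lone, NULL)
  }
  logits <- classifier_forward(model$fusion, fu$fused, train = train)
  list(logits = logits, fused = fu$fused)
}

#' Predicted ASD probabilities for a set of subjects
#'
#' Deterministic evaluation-mode forward pass of the full model.
#'
#' @param model a [ds_model()].
#' @param records list of [subject_record()].
#' @return numeric vector of P(ASD) per subject.
#' @export
predict_scores <- function(model, records) {
  out <- numeric(length(records))
  for (k in seq_along(records)) {
    ag_reset()
    x <- records[[k]]$series
    p <- if (model$backbone != "tst1") flatten_upper(compute_pcc(x))
    fw <- model_forward_one(model, x = x, p = p, train = FALSE)
    lv <- as.numeric(fw$logits$v)
    e <- exp(lv - max(lv))
    out[k] <- (e / sum(e))[2]
  }
  ag_reset()
  out
}

# all trainable parameter leaves of the model under a freezing policy
model_trainables <- function(model, freeze = freeze_policy("none"),
                             freeze_proj_heads = FALSE) {
  tr <- model$fusion$params
  if (model$use_heads && !freeze_proj_heads) {
    if (model$backbone != "tst2") tr <- c(tr, model$head1$params)
    if (model$backbone != "tst1") tr <- c(tr, model$head2$params)
  }
  if (model$backbone != "tst2" && !freeze$freeze_tst1) {
    tr <- c(tr, model$tst1$params)
  }
  if (model$backbone != "tst1" && !freeze$freeze_tst2) {
    tr <- c(tr, model$tst2$params)
  }
  tr
}
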