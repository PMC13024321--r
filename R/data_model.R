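#' Construct a subject record
#'
#' A subject record bundles one subject's ROI time-series matrix (T time
#' points x R ROIs, arbitrary BOLD units) with its diagnosis label and
#' acquisition site. Validation enforces the quality-control rules applied to
#' real cohorts: at least 3 time points, at least 2 ROIs, finite entries, and
#' no constant (zero-variance) ROI column — a constant column indicates
#' missing or corrupted parcel data and makes the Pearson correlation
#' undefined.
#'
#' @param subject_id character scalar, unique subject identifier.
#' @param label integer 0 (typically developing, TD) or 1 (ASD).
#' @param site character scalar, acquisition site identifier.
#' @param series numeric matrix, T x R.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, label, site, series) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 (TD) or 1 (ASD)")
  series <- as.matrix(series)
  if (nrow(series) < 3L) stop("series must have at least 3 time points")
  if (ncol(series) < 2L) stop("series must have at least 2 ROIs")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  v <- apply(series, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI column(s): ", paste(which(v == 0), collapse = ", "))
  }
  structure(
    list(subject_id = subject_id, label = label, site = as.character(site),
         series = series),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s: label=%d site=%s series %dx%d>\n",
              x$subject_id, x$label, x$site, nrow(x$series), ncol(x$series)))
  invisible(x)
}

parse_label <- function(tok) {
  tok <- as.character(tok)
  out <- ifelse(tok %in% c("ASD", "1"), 1L,
                ifelse(tok %in% c("TD", "0"), 0L, NA_integer_))
  if (anyNA(out)) {
    stop("unknown label token(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "),
         " (expected ASD/TD or 1/0)")
  }
  out
}

#' Read a dataset manifest
#'
#' The manifest is a tab-separated file with header columns
#' `subject_id`, `label`, `site`, `path`. Labels may be `ASD`/`TD` or `1`/`0`.
#' Paths are resolved relative to the manifest's directory unless absolute.
#'
#' @param path path to the manifest TSV.
#' @return A `ds_manifest`: data frame of records plus the manifest directory.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "label", "site", "path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  lab <- parse_label(df$label)
  if (length(unique(lab)) < 2L) stop("manifest must contain both labels")
  records <- data.frame(subject_id = df$subject_id, label = lab,
                        site = df$site, path = df$path,
                        stringsAsFactors = FALSE)
  structure(list(records = records, dir = dirname(path)), class = "ds_manifest")
}

#' @export
print.ds_manifest <- function(x, ...) {
  cat(sprintf("<ds_manifest: %d subjects (%d ASD / %d TD), %d sites>\n",
              nrow(x$records), sum(x$records$label == 1L),
              sum(x$records$label == 0L), length(unique(x$records$site))))
  invisible(x)
}

#' Write a dataset manifest
#' @param manifest a `ds_manifest`.
#' @param path output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Delimited numeric matrix, no header: tab-, comma- or whitespace-separated.
read_series <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}

#' Load subject records listed in a manifest
#'
#' Reads each subject's series matrix and applies quality control: any subject
#' whose matrix contains a zero-variance ROI column (which subsumes the
#' all-zero case) is excluded with a warning, mirroring the exclusion of
#' subjects with missing parcel coverage in real cohorts.
#'
#' @param manifest a `ds_manifest`.
#' @return list of `subject_record`, possibly shorter than the manifest.
#' @export
load_subjects <- function(manifest) {
  recs <- manifest$records
  out <- vector("list", nrow(recs))
  keep <- logical(nrow(recs))
  for (k in seq_len(nrow(recs))) {
    p <- recs$path[k]
    if (!file.exists(p)) p <- file.path(manifest$dir, recs$path[k])
    if (!file.exists(p)) stop("series file not found: ", recs$path[k])
    series <- read_series(p)
    v <- apply(series, 2L, stats::var)
    if (any(!is.finite(series)) || any(v == 0)) {
      warning(sprintf("QC: excluding subject %s (zero-variance or non-finite ROI)",
                      recs$subject_id[k]))
      next
    }
    out[[k]] <- subject_record(recs$subject_id[k], recs$label[k],
                               recs$site[k], series)
    keep[k] <- TRUE
  }
  out[keep]
}

#' Pearson correlation matrix of ROI time series
#'
#' Computes the R x R matrix of Pearson correlation coefficients between all
#' pairs of ROI columns — the static functional connectivity of the subject.
#'
#' @param series numeric matrix, T x R, T >= 3, no zero-variance column.
#' @return symmetric R x R correlation matrix with unit diagonal.
#' @export
compute_pcc <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) stop("need at least 3 time points")
  v <- apply(series, 2L, stats::var)
  if (any(v == 0)) {
    stop("degenerate input: zero-variance column(s) ",
         paste(which(v == 0), collapse = ", "))
  }
  p <- stats::cor(series)
  diag(p) <- 1
  p
}

# Row-major strict upper-triangle (i < j) index pairs for R ROIs, in the fixed
# edge ordering shared by every module: (1,2), (1,3), ..., (1,R), (2,3), ...
upper_pairs <- function(R) {
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Flatten the strict upper triangle of a symmetric matrix
#'
#' Extracts the R(R-1)/2 above-diagonal entries in row-major order (i < j,
#' i ascending, then j). This ordering is the package-wide edge <-> index
#' convention used by the connectivity encoder and the interpretability
#' module.
#'
#' @param m square symmetric numeric matrix (symmetry tolerance `tol`).
#' @param tol symmetry tolerance, default 1e-6.
#' @return numeric vector of length R(R-1)/2.
#' @export
flatten_upper <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol) stop("matrix asymmetric beyond tolerance")
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from a flattened upper triangle
#'
#' Inverse of [flatten_upper()]: places the vector back on both triangles and
#' sets a unit diagonal (the correlation-matrix convention).
#'
#' @param v numeric vector whose length is R(R-1)/2 for some integer R.
#' @return symmetric R x R matrix with unit diagonal.
#' @export
unflatten_upper <- function(v) {
  D <- length(v)
  R <- (1 + sqrt(1 + 8 * D)) / 2
  if (abs(R - round(R)) > 1e-9) {
    stop("length ", D, " is not R(R-1)/2 for any integer R")
  }
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  m[lower.tri(m)] <- v      # column-major lower fill == row-major upper order
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

# Map edge (i, j), i < j, to its position in the flattened vector.
edge_index <- function(i, j, R) {
  stopifnot(all(i < j), all(j <= R))
  (i - 1L) * R - i * (i - 1L) / 2L + (j - i)
}
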