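#' Configuration for the synthetic multi-site connectome generator
#'
#' Describes a two-group, multi-site population of ROI time series with a
#' controlled group difference in functional connectivity. Each subject's
#' series is drawn from a zero-mean multivariate normal whose correlation
#' matrix is the identity except on a designated edge set, where the TD group
#' has correlation `base_r` and the ASD group `base_r + delta_r`; temporal
#' structure is added by an AR(1) filter whose stationary marginal
#' distribution preserves the target instantaneous correlation.
#'
#' @param n_subjects total number of subjects (classes balanced to within 1).
#' @param R number of ROIs.
#' @param T_len number of time points per subject.
#' @param n_sites number of pseudo-sites, assigned round-robin within class so
#'   every site receives both classes whenever `n_subjects` permits.
#' @param edge_set two-column matrix of (i, j) ROI pairs with i < j; default:
#'   all pairs among the first 5 ROIs (a single connected block).
#' @param delta_r target ASD-minus-TD correlation difference on the edge set,
#'   in (0, 1].
#' @param base_r TD baseline correlation on the edge set, in [0, 1).
#' @param ar_coeff lag-1 temporal autocorrelation in [0, 1). The default 0.5
#'   reflects the smoothness of band-pass-filtered BOLD at typical repetition
#'   times.
#' @param site_mean_sd,site_scale_sd optional per-site additive mean offset
#'   (sd of the site means) and multiplicative scale spread; both default to 0
#'   (no site effect) and exist to exercise cross-site distribution shift.
#' @param seed integer seed; the generated dataset is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects, R = 20L, T_len = 100L, n_sites = 3L,
                       edge_set = NULL, delta_r = 0.5, base_r = 0.1,
                       ar_coeff = 0.5, site_mean_sd = 0, site_scale_sd = 0,
                       seed = 1L) {
  if (is.null(edge_set)) {
    b <- min(5L, R)
    edge_set <- upper_pairs(b)
  }
  edge_set <- as.matrix(edge_set)
  stopifnot(n_subjects >= 2, R >= 2, T_len >= 3, n_sites >= 1,
            ncol(edge_set) == 2, all(edge_set[, 1] < edge_set[, 2]),
            all(edge_set[, 2] <= R),
            delta_r >= 0, delta_r <= 1,
            base_r >= 0, base_r < 1,
            ar_coeff >= 0, ar_coeff < 1)
  if (base_r + delta_r >= 1) stop("base_r + delta_r must be < 1")
  structure(
    list(n_subjects = as.integer(n_subjects), R = as.integer(R),
         T_len = as.integer(T_len), n_sites = as.integer(n_sites),
         edge_set = edge_set, delta_r = delta_r, base_r = base_r,
         ar_coeff = ar_coeff, site_mean_sd = site_mean_sd,
         site_scale_sd = site_scale_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Group correlation matrix: identity plus r on the edge set. If the result is
# not positive definite it is repaired by nearest-PD projection; the repair
# must not move any targeted entry by more than 0.05.
group_correlation <- function(R, edge_set, r) {
  S <- diag(R)
  for (k in seq_len(nrow(edge_set))) {
    i <- edge_set[k, 1]; j <- edge_set[k, 2]
    S[i, j] <- r; S[j, i] <- r
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    warning("target correlation matrix not positive definite; applying nearest-PD repair")
    Sp <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
    shift <- max(abs(Sp[edge_set] - S[edge_set]))
    if (shift > 0.05) {
      stop("nearest-PD repair moved a target correlation by ",
           signif(shift, 3), " (> 0.05); choose a feasible edge set / base_r")
    }
    S <- Sp
  }
  S
}

#' Simulate a labeled multi-site dataset of ROI time series
#'
#' Generates `n_subjects` subject records under the model described in
#' [sim_config()]. The AR(1) filter is applied after the spatial correlation
#' is imposed, as `x_t = phi x_(t-1) + sqrt(1 - phi^2) e_t` with innovations
#' `e_t ~ N(0, Sigma_group)`, so the stationary marginal covariance of every
#' time point equals `Sigma_group` exactly and the target instantaneous
#' correlations are preserved in expectation.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, per-subject series are
#'   written as headerless TSV matrices and a manifest TSV is written
#'   alongside.
#' @return list with `records` (list of [subject_record()]) and `manifest`
#'   (a `ds_manifest`; paths populated only when `dir` is given).
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(.restore_seed(old), add = TRUE)

  n <- cfg$n_subjects
  labels <- rep(c(0L, 1L), length.out = n)     # balanced to within 1
  # round-robin site assignment within class
  sites <- integer(n)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    sites[idx] <- ((seq_along(idx) - 1L) %% cfg$n_sites) + 1L
  }
  site_names <- sprintf("site%02d", sites)

  S_td <- group_correlation(cfg$R, cfg$edge_set, cfg$base_r)
  S_asd <- group_correlation(cfg$R, cfg$edge_set, cfg$base_r + cfg$delta_r)
  U <- list(`0` = chol(S_td), `1` = chol(S_asd))

  site_mu <- stats::rnorm(cfg$n_sites, 0, cfg$site_mean_sd)
  site_sc <- exp(stats::rnorm(cfg$n_sites, 0, cfg$site_scale_sd))

  phi <- cfg$ar_coeff
  innov_scale <- sqrt(1 - phi^2)
  records <- vector("list", n)
  for (s in seq_len(n)) {
    E <- matrix(stats::rnorm(cfg$T_len * cfg$R), cfg$T_len) %*%
      U[[as.character(labels[s])]]
    X <- E
    if (phi > 0) {
      for (t in 2:cfg$T_len) X[t, ] <- phi * X[t - 1L, ] + innov_scale * E[t, ]
    }
    X <- X * site_sc[sites[s]] + site_mu[sites[s]]
    records[[s]] <- subject_record(sprintf("sub%04d", s), labels[s],
                                   site_names[s], X)
  }

  paths <- rep("", n)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(n)) {
      paths[s] <- file.path(dir, sprintf("%s.tsv", records[[s]]$subject_id))
      utils::write.table(records[[s]]$series, paths[s], sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  manifest <- structure(
    list(records = data.frame(
      subject_id = vapply(records, `[[`, "", "subject_id"),
      label = labels, site = site_names, path = paths,
      stringsAsFactors = FALSE),
      dir = if (is.null(dir)) "." else dir),
    class = "ds_manifest")
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.tsv"))
  list(records = records, manifest = manifest)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Stratified train/validation/test split
#'
#' Splits subjects into three disjoint, exhaustive partitions, stratified by
#' label with largest-remainder rounding so the realised per-class counts
#' match the requested fractions as closely as integer counts allow.
#'
#' @param records list of [subject_record()] (or a `ds_manifest`).
#' @param fractions length-3 positive numeric summing to 1 (within 1e-9),
#'   ordered (train, validation, test).
#' @param seed integer seed controlling the shuffle.
#' @return list with elements `train`, `val`, `test` of the same type as the
#'   input.
#' @export
split_dataset <- function(records, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  is_manifest <- inherits(records, "ds_manifest")
  labels <- if (is_manifest) records$records$label
            else vapply(records, `[[`, 0L, "label")
  n <- length(labels)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  part <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < 3L) {
      stop("stratification error: class ", cl, " has fewer subjects (",
           length(idx), ") than partitions")
    }
    cuts <- floor(cumsum(fractions) * length(idx) + 1e-9)
    sizes <- diff(c(0L, cuts))
    part[idx] <- rep.int(1:3, sizes)
  }
  pick <- function(k) {
    if (is_manifest) {
      structure(list(records = records$records[part == k, , drop = FALSE],
                     dir = records$dir), class = "ds_manifest")
    } else {
      records[part == k]
    }
  }
  list(train = pick(1L), val = pick(2L), test = pick(3L))
}
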