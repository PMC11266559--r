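#' Median-normalize columns of a log2 abundance matrix
#'
#' Subtracts the per-sample median of observed values from every column, so
#' each column's median becomes 0. This compensates loading/injection
#' differences between samples. Missingness is untouched.
#'
#' @param m an [abundance_matrix()] or numeric matrix of log2 abundances.
#' @return The same type as `m`, column-median-centered.
#' @export
median_normalize_columns <- function(m) {
  v <- as_values(m)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  bad <- !is.finite(med)
  if (any(bad))
    stop("column(s) with no observed values: ",
         paste(colnames(v)[bad], collapse = ", "))
  rewrap(m, sweep(v, 2, med))
}

#' Center rows at their observed mean
#'
#' Subtracts the per-feature mean of observed values, mimicking SILAC-style
#' ratios after batch correction. All-missing rows are retained as-is with a
#' warning.
#'
#' @inheritParams median_normalize_columns
#' @return Row-mean-centered matrix of the same type.
#' @export
row_mean_center <- function(m) {
  v <- as_values(m)
  mu <- rowMeans(v, na.rm = TRUE)
  empty <- !is.finite(mu)
  if (any(empty)) {
    warning(sum(empty), " all-missing row(s) retained unchanged")
    mu[empty] <- 0
  }
  rewrap(m, sweep(v, 1, mu))
}

#' Equalize batch locations (and scales) per missingness-dissection block
#'
#' Rows are dissected into blocks by their pattern of *covered* batches (a
#' batch covers a row when it holds at least 2 observed values). Within each
#' row, every covered batch's mean (and, in `location_scale` mode, standard
#' deviation) is equalized to the pooled mean (sd) over all covered batches.
#' Rows covered by fewer than two batches pass through unchanged. Missing
#' entries are never imputed. A batch holding exactly one observed value has
#' undefined variance: in `location` mode that value is mean-adjusted like any
#' covered batch (it maps onto the pooled mean); in `location_scale` mode it
#' passes through unchanged.
#'
#' @param m an [abundance_matrix()] with a `batch` vector, or a numeric matrix
#'   plus `batch`.
#' @param mode `"location"` or `"location_scale"`.
#' @param batch per-sample batch labels; defaults to `m$batch`.
#' @return Batch-adjusted matrix of the same type as `m`. The attribute
#'   `"blocks"` records the dissection pattern of each row.
#' @export
dissect_and_adjust_batches <- function(m, mode = c("location", "location_scale"),
                                       batch = NULL) {
  mode <- match.arg(mode)
  v <- as_values(m)
  if (is.null(batch)) batch <- if (inherits(m, "abundance_matrix")) m$batch else NULL
  if (is.null(batch)) stop("batch labels are required")
  batch <- as.character(batch)
  if (length(batch) != ncol(v)) stop("`batch` must have one label per sample")
  batches <- unique(batch)
  if (length(batches) < 2) stop("need at least 2 batches")

  cols_by_batch <- lapply(batches, function(b) which(batch == b))
  names(cols_by_batch) <- batches
  out <- v
  # per-row coverage pattern: batches with >= 2 observed values
  nobs <- vapply(cols_by_batch, function(ix) rowSums(!is.na(v[, ix, drop = FALSE])),
                 numeric(nrow(v)))
  if (nrow(v) == 1) nobs <- matrix(nobs, nrow = 1, dimnames = list(NULL, batches))
  covered <- nobs >= 2
  pattern <- apply(covered, 1, function(z) paste(batches[z], collapse = "|"))

  for (i in seq_len(nrow(v))) {
    cov_b <- batches[covered[i, ]]
    # singleton batches join coverage in location mode (mean of 1 value is defined)
    if (mode == "location") cov_b <- batches[nobs[i, ] >= 1]
    if (sum(covered[i, ]) < 2 && mode == "location_scale") next
    if (length(cov_b) < 2) next
    pool_idx <- unlist(cols_by_batch[cov_b], use.names = FALSE)
    pooled <- v[i, pool_idx]
    pooled_mean <- mean(pooled, na.rm = TRUE)
    if (mode == "location_scale") {
      bvars <- vapply(cov_b, function(b) stats::var(v[i, cols_by_batch[[b]]], na.rm = TRUE), 0)
      bdf <- nobs[i, cov_b] - 1
      pooled_sd <- sqrt(sum(bvars * bdf) / sum(bdf))
    }
    for (b in cov_b) {
      ix <- cols_by_batch[[b]]
      x <- v[i, ix]
      bm <- mean(x, na.rm = TRUE)
      if (mode == "location") {
        out[i, ix] <- x - bm + pooled_mean
      } else {
        bs <- stats::sd(x, na.rm = TRUE)
        scale <- if (is.na(bs) || bs == 0 || pooled_sd == 0) 1 else pooled_sd / bs
        out[i, ix] <- (x - bm) * scale + pooled_mean
      }
    }
  }
  res <- rewrap(m, out)
  attr(res, "blocks") <- pattern
  res
}

#' Merge abundance matrices on the UniProt key
#'
#' Row union keyed by feature id; entries absent from a source dataset are
#' missing. Column order follows input order; a per-sample dataset label is
#' recorded.
#'
#' @param ... [abundance_matrix()] objects or named matrices, optionally named
#'   (names become dataset labels; defaults `dataset1`, `dataset2`, ...).
#' @return An [abundance_matrix()] with `dataset` set.
#' @export
merge_datasets <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "abundance_matrix") &&
      !is.matrix(ms[[1]])) ms <- ms[[1]]
  if (length(ms) == 0) stop("no input matrices")
  labs <- names(ms)
  if (is.null(labs)) labs <- rep("", length(ms))
  labs <- ifelse(labs == "", paste0("dataset", seq_along(ms)), labs)
  vs <- lapply(ms, as_values)
  all_samples <- unlist(lapply(vs, colnames), use.names = FALSE)
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup))
    stop("duplicate sample id(s) across datasets: ", paste(unique(dup), collapse = ", "))
  all_feats <- unique(unlist(lapply(vs, rownames), use.names = FALSE))
  out <- matrix(NA_real_, length(all_feats), length(all_samples),
                dimnames = list(all_feats, all_samples))
  dataset <- character(0)
  batch <- character(0)
  has_batch <- FALSE
  for (j in seq_along(ms)) {
    out[rownames(vs[[j]]), colnames(vs[[j]])] <- vs[[j]]
    dataset <- c(dataset, rep(labs[j], ncol(vs[[j]])))
    b <- if (inherits(ms[[j]], "abundance_matrix") && !is.null(ms[[j]]$batch))
      ms[[j]]$batch else rep(NA_character_, ncol(vs[[j]]))
    if (!all(is.na(b))) has_batch <- TRUE
    batch <- c(batch, b)
  }
  abundance_matrix(out, batch = if (has_batch) batch else NULL, dataset = dataset)
}

#' Filter features by fraction of observed values
#'
#' Retains rows whose observed (non-missing) fraction is at least `min_frac`,
#' either over all samples (`scope = "global"`) or within every group
#' (`scope = "per_group"`). The threshold is inclusive.
#'
#' @inheritParams median_normalize_columns
#' @param min_frac required observed fraction, in (0, 1].
#' @param scope `"global"` or `"per_group"`.
#' @param groups per-sample group labels, required for `per_group`.
#' @return Filtered matrix of the same type.
#' @export
filter_validity <- function(m, min_frac, scope = c("global", "per_group"),
                            groups = NULL) {
  scope <- match.arg(scope)
  stopifnot(min_frac > 0, min_frac <= 1)
  v <- as_values(m)
  if (scope == "global") {
    keep <- rowMeans(!is.na(v)) >= min_frac
  } else {
    if (is.null(groups)) stop("`groups` required when scope = 'per_group'")
    if (length(groups) != ncol(v)) stop("`groups` must have one label per sample")
    keep <- rep(TRUE, nrow(v))
    for (g in unique(groups)) {
      ix <- which(groups == g)
      keep <- keep & rowMeans(!is.na(v[, ix, drop = FALSE])) >= min_frac
    }
  }
  if (!any(keep))
    stop("no feature passes min_frac = ", min_frac, "; consider a lower threshold")
  out <- v[keep, , drop = FALSE]
  rewrap(m, out)
}

#' Flag samples with elevated blood-panel signal
#'
#' Computes each sample's mean abundance over a blood-protein panel and flags
#' samples exceeding the cohort mean by more than `z_thresh` cohort standard
#' deviations. Exclusion is left to the caller.
#'
#' @inheritParams median_normalize_columns
#' @param panel character vector of panel feature ids (>= 1 must be present).
#' @param z_thresh flag threshold in cohort standard deviations.
#' @return Named logical vector over samples; attribute `"z"` holds the
#'   per-sample z-scores.
#' @export
flag_contaminated_samples <- function(m, panel, z_thresh = 3) {
  v <- as_values(m)
  panel <- intersect(panel, rownames(v))
  if (length(panel) == 0) stop("no panel protein present in the matrix")
  s <- colMeans(v[panel, , drop = FALSE], na.rm = TRUE)
  mu <- mean(s, na.rm = TRUE)
  sd0 <- stats::sd(s, na.rm = TRUE)
  z <- if (is.na(sd0) || sd0 == 0) rep(0, length(s)) else (s - mu) / sd0
  names(z) <- colnames(v)
  flags <- z > z_thresh
  flags[is.na(flags)] <- FALSE
  attr(flags, "z") <- z
  flags
}
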