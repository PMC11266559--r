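#' Missing-value-tolerant pairwise-complete distances between samples
#'
#' Correlation metrics return `1 - r` computed over the pairwise non-missing
#' rows of each sample pair; Euclidean distances are rescaled by
#' `sqrt(n_total / n_observed)` so sparsity does not shrink them. Pairs with
#' fewer than `min_overlap` shared observations get the metric's maximal
#' distance (2 for correlations) with a warning.
#'
#' @param m an [abundance_matrix()] or features x samples matrix.
#' @param metric `"euclidean"`, `"pearson"` or `"spearman"`.
#' @param min_overlap minimum shared observed features per pair.
#' @return A symmetric `n_samples x n_samples` matrix of distances with zero
#'   diagonal.
#' @export
pairwise_complete_distance <- function(m, metric = c("pearson", "spearman", "euclidean"),
                                       min_overlap = 5) {
  metric <- match.arg(metric)
  v <- as_values(m)
  if (ncol(v) < 2) stop("need at least 2 samples")
  allmiss <- colSums(!is.na(v)) == 0
  if (any(allmiss))
    stop("sample(s) with all-missing values: ",
         paste(colnames(v)[allmiss], collapse = ", "))
  obs <- !is.na(v)
  overlap <- crossprod(obs)
  if (metric %in% c("pearson", "spearman")) {
    r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                     method = metric))
    d <- 1 - r
    bad <- overlap < min_overlap | !is.finite(d)
    diag(bad) <- FALSE
    if (any(bad)) {
      warning(sum(bad) / 2, " sample pair(s) below min_overlap or with ",
              "undefined correlation set to maximal distance 2")
      d[bad] <- 2
    }
  } else {
    n_feat <- nrow(v)
    v0 <- v; v0[!obs] <- 0
    # sum((x-y)^2) over shared rows via cross-products; zeros mask the gaps
    xy <- crossprod(v0)                 # sum x_i y_i over shared rows
    x2 <- crossprod(v0^2, obs)          # sum x_i^2 over rows observed in y
    ss <- x2 + t(x2) - 2 * xy
    ss[ss < 0] <- 0
    d <- sqrt(ss * n_feat / pmax(overlap, 1))
    bad <- overlap < min_overlap
    diag(bad) <- FALSE
    if (any(bad)) {
      warning(sum(bad) / 2, " sample pair(s) below min_overlap set to ",
              "maximal observed distance")
      d[bad] <- max(d[!bad], 0)
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(v), colnames(v))
  d
}

cluster_from_distance <- function(d, k, method = c("hclust_ward", "pam")) {
  method <- match.arg(method)
  dd <- stats::as.dist(d)
  if (method == "hclust_ward") {
    stats::cutree(stats::hclust(dd, method = "ward.D2"), k = k)
  } else {
    cluster::pam(dd, k = k, cluster.only = TRUE)
  }
}

#' Consensus matrix over subsampled clusterings
#'
#' Repeatedly clusters a random subset of samples and records, for every
#' sample pair, how often it was co-clustered among the resamples containing
#' both. Final assignments come from Ward clustering of `1 - consensus`.
#'
#' @inheritParams pairwise_complete_distance
#' @param k number of clusters.
#' @param n_resamples number of subsampling iterations.
#' @param item_frac fraction of samples drawn (without replacement) per
#'   iteration.
#' @param method `"hclust_ward"` (Ward.D2 linkage) or `"pam"` (k-medoids).
#' @param seed integer seed; the full procedure is deterministic given it.
#' @param dist optional precomputed distance matrix (as from
#'   [pairwise_complete_distance()]); pairwise distances do not depend on the
#'   subsample, so it is computed once.
#' @return A list of class `consensus_result`: `k`, `consensus` (NaN where a
#'   pair was never co-sampled), `co_sampled`, `assignments`, `pac`, `method`,
#'   `metric`.
#' @export
consensus_matrix <- function(m, k, n_resamples = 1000, item_frac = 0.8,
                             method = c("hclust_ward", "pam"),
                             metric = c("pearson", "spearman", "euclidean"),
                             seed = 1, min_overlap = 5, dist = NULL) {
  method <- match.arg(method); metric <- match.arg(metric)
  if (is.null(dist)) dist <- pairwise_complete_distance(m, metric, min_overlap)
  n <- ncol(dist)
  if (k < 2 || k > n - 1) stop("k must lie in [2, n_samples - 1]")
  stopifnot(item_frac > 0, item_frac <= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  n_sub <- ceiling(item_frac * n)
  co_cluster <- matrix(0L, n, n)
  co_sampled <- matrix(0L, n, n)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, n_sub))
    cl <- NULL
    for (retry in 1:10) {
      cl <- tryCatch(cluster_from_distance(dist[idx, idx], k, method),
                     error = function(e) NULL)
      if (!is.null(cl) && length(unique(cl)) == k) break
      idx <- sort(sample.int(n, n_sub))
    }
    if (is.null(cl)) stop("clustering failed repeatedly at resample ", b)
    same <- outer(cl, cl, "==")
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    co_cluster[idx, idx] <- co_cluster[idx, idx] + same
  }
  consensus <- co_cluster / co_sampled   # NaN where never co-sampled
  diag(consensus) <- 1
  dimnames(consensus) <- dimnames(co_sampled) <- dimnames(dist)
  cd <- 1 - consensus
  cd[!is.finite(cd)] <- 1                # never co-sampled: maximal uncertainty
  assignments <- stats::cutree(stats::hclust(stats::as.dist(cd), "ward.D2"), k)
  res <- structure(list(k = k, consensus = consensus, co_sampled = co_sampled,
                        assignments = assignments, method = method,
                        metric = metric),
                   class = "consensus_result")
  res$pac <- pac(res)
  res
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The fraction of off-diagonal, co-sampled consensus entries lying strictly
#' inside `(lower, upper)`. Lower PAC indicates a more stable cluster number.
#'
#' @param c a `consensus_result` or a consensus matrix.
#' @param lower,upper open-interval bounds, `0 < lower < upper < 1`.
#' @return PAC score in `[0, 1]`.
#' @export
pac <- function(c, lower = 0.1, upper = 0.9) {
  stopifnot(lower < upper, lower > 0, upper < 1)
  if (inherits(c, "consensus_result")) {
    cm <- c$consensus
    ok <- c$co_sampled >= 1
  } else {
    cm <- c
    ok <- is.finite(cm)
  }
  off <- upper.tri(cm)
  vals <- cm[off & ok & is.finite(cm)]
  if (length(vals) == 0) stop("no co-sampled off-diagonal pairs")
  mean(vals > lower & vals < upper)
}

#' Select the cluster number minimizing PAC
#'
#' @param pac_by_k named numeric vector (names = k) or list mapping k to PAC.
#' @return The k with minimal PAC; ties broken toward smaller k.
#' @export
select_k <- function(pac_by_k) {
  v <- unlist(pac_by_k)
  ks <- as.integer(names(v))
  if (any(is.na(ks))) stop("pac_by_k must be named by k")
  o <- order(ks)
  ks <- ks[o]; v <- v[o]
  ks[which.min(v)]
}

# Align labels of `cl` to `ref` by maximum-overlap bipartite matching on the
# contingency table. Exact (all permutations) for k <= 8, greedy otherwise.
align_labels <- function(cl, ref, k) {
  tab <- matrix(0L, k, k)
  for (i in seq_along(cl)) tab[cl[i], ref[i]] <- tab[cl[i], ref[i]] + 1L
  if (k <= 8) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(tab[cbind(seq_len(k), p)]), 0L)
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k); taken <- logical(k); t2 <- tab
    for (step in seq_len(k)) {
      ij <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
      best[ij[1]] <- ij[2]
      t2[ij[1], ] <- -1L; t2[, ij[2]] <- -1L
    }
  }
  best[cl]
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(k)) {
    i <- i + 1L
    out[[i]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Cluster-certainty vote over six metric-method combinations
#'
#' Clusters the full data with each of the 6 combinations of two methods
#' (Ward hierarchical, k-medoids) and three pairwise-complete distance
#' metrics (Euclidean, Spearman, Pearson) at fixed `k`, aligns each run's
#' labels to the first run by maximum-overlap matching, and reports per
#' sample how many runs agree with its modal cluster.
#'
#' @inheritParams pairwise_complete_distance
#' @param k number of clusters (default 6).
#' @return A list: `certainty` (named integer vector, 0..n_runs), `modal`
#'   (modal aligned assignment), `votes` (runs x samples matrix of aligned
#'   labels), `n_runs` (denominator; 6 unless runs failed), `tied` (logical,
#'   samples whose vote was split without a unique mode).
#' @export
certainty_vote <- function(m, k = 6, min_overlap = 5) {
  combos <- expand.grid(method = c("hclust_ward", "pam"),
                        metric = c("euclidean", "spearman", "pearson"),
                        stringsAsFactors = FALSE)
  dists <- lapply(unique(combos$metric), function(mt)
    pairwise_complete_distance(m, mt, min_overlap))
  names(dists) <- unique(combos$metric)
  runs <- list()
  for (i in seq_len(nrow(combos))) {
    cl <- tryCatch(cluster_from_distance(dists[[combos$metric[i]]], k,
                                         combos$method[i]),
                   error = function(e) NULL)
    if (!is.null(cl)) runs[[length(runs) + 1]] <- cl
  }
  if (length(runs) == 0) stop("all certainty runs failed")
  if (length(runs) < nrow(combos))
    warning("certainty computed over ", length(runs), "/", nrow(combos), " runs")
  ref <- as.integer(runs[[1]])
  votes <- t(vapply(runs, function(cl)
    as.integer(align_labels(as.integer(cl), ref, k)),
    integer(length(ref))))
  colnames(votes) <- names(runs[[1]]) %||% colnames(as_values(m))
  n_runs <- nrow(votes)
  modal <- integer(ncol(votes)); cert <- integer(ncol(votes)); tied <- logical(ncol(votes))
  for (j in seq_len(ncol(votes))) {
    tb <- table(votes[, j])
    cert[j] <- max(tb)
    winners <- names(tb)[tb == max(tb)]
    tied[j] <- length(winners) > 1
    modal[j] <- as.integer(winners[1])
  }
  names(modal) <- names(cert) <- names(tied) <- colnames(votes)
  list(certainty = cert, modal = modal, votes = votes, n_runs = n_runs,
       tied = tied)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stepwise k-means profile hierarchy
#'
#' Runs k-means for k = 2..`k_max` on validity-filtered, row-mean-imputed
#' data and links each k-level cluster to its parent at level k-1 by maximal
#' sample overlap. The k = 2 partition defines the two superordinate
#' profiles.
#'
#' @inheritParams pairwise_complete_distance
#' @param k_max deepest level (default 6).
#' @param min_frac validity filter applied before imputation (k-means cannot
#'   handle missing values); remaining gaps are replaced by row means.
#' @param nstart k-means restarts.
#' @param seed integer seed.
#' @return A list of class `profile_hierarchy`: `partitions` (list by k),
#'   `edges` (data.frame k, cluster, parent_cluster, overlap), `profiles`
#'   (the k = 2 labels).
#' @export
profile_hierarchy <- function(m, k_max = 6, min_frac = 0.7, nstart = 25,
                              seed = 1) {
  v <- as_values(filter_validity(m, min_frac, "global"))
  rm <- rowMeans(v, na.rm = TRUE)
  for (i in seq_len(nrow(v))) v[i, is.na(v[i, ])] <- rm[i]
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  x <- t(v)  # samples x features
  partitions <- list()
  for (k in 2:k_max) {
    km <- NULL
    for (retry in 1:10) {
      km <- tryCatch(stats::kmeans(x, centers = k, nstart = nstart,
                                   iter.max = 100),
                     error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) stop("k-means failed at k = ", k)
    partitions[[as.character(k)]] <- stats::setNames(km$cluster, rownames(x))
  }
  edges <- NULL
  for (k in seq_len(k_max)[-seq_len(2)]) {
    child <- partitions[[as.character(k)]]
    parent <- partitions[[as.character(k - 1)]]
    for (cl in sort(unique(child))) {
      ov <- table(parent[child == cl])
      best <- names(ov)[which.max(ov)]
      edges <- rbind(edges, data.frame(k = k, cluster = cl,
                                       parent_cluster = as.integer(best),
                                       overlap = max(ov)))
    }
  }
  structure(list(partitions = partitions, edges = edges,
                 profiles = partitions[["2"]]),
            class = "profile_hierarchy")
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Full PAC model-selection sweep
#'
#' Convenience wrapper running [consensus_matrix()] for a range of k over one
#' method/metric combination and collecting PAC scores.
#'
#' @inheritParams consensus_matrix
#' @param k_range integer vector of candidate cluster numbers.
#' @return A list: `pac_by_k` (named vector), `best_k`, `results` (list of
#'   `consensus_result` by k).
#' @export
pac_sweep <- function(m, k_range = 2:12, n_resamples = 1000, item_frac = 0.8,
                      method = "hclust_ward", metric = "pearson", seed = 1,
                      min_overlap = 5) {
  dist <- pairwise_complete_distance(m, metric, min_overlap)
  results <- list()
  pac_by_k <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    results[[as.character(k)]] <- consensus_matrix(
      m, k, n_resamples, item_frac, method, metric,
      seed = seed + k, dist = dist)
    pac_by_k[i] <- results[[as.character(k)]]$pac
  }
  list(pac_by_k = pac_by_k, best_k = select_k(pac_by_k), results = results)
}
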