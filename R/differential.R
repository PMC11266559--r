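#' Two-group t test on observed values
#'
#' Thin wrapper around [stats::t.test()] returning the statistic (sign:
#' `mean(x) - mean(y)`) and the two-tailed p value. Groups with fewer than 2
#' observed values are untestable.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @param variant `"student"` (pooled variance) or `"welch"` (Satterthwaite
#'   degrees of freedom).
#' @return A list: `statistic`, `p`, `df`, `testable`.
#' @export
t_test_two_group <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(statistic = NA_real_, p = NA_real_, df = NA_real_,
                testable = FALSE))
  df0 <- length(x) + length(y) - 2
  if (stats::sd(c(x, y)) == 0)
    return(list(statistic = 0, p = 1, df = df0, testable = TRUE))
  if (stats::sd(x) == 0 && stats::sd(y) == 0)  # constant but separated groups
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p = 0, df = df0,
                testable = TRUE))
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), testable = TRUE)
}

#' One-vs-rest differential abundance table for one subtype
#'
#' Tests each feature's abundance in the target subtype against all other
#' samples with a two-tailed t test, after restricting to features observed
#' in at least `min_frac` of the samples of every group. A feature is
#' significant when `p < p_thresh` and `|log2fc| > fc_thresh`, with `log2fc`
#' the in-minus-out mean difference on the log2 scale.
#'
#' @param m an [abundance_matrix()] or matrix of log2 abundances.
#' @param labels per-sample group labels.
#' @param target the subtype tested against the rest.
#' @param p_thresh,fc_thresh significance thresholds.
#' @param min_frac per-group validity fraction (inclusive).
#' @param variant t-test variant, see [t_test_two_group()].
#' @return data.frame with one row per tested feature: `feature`, `mean_in`,
#'   `mean_out`, `mean_diff`, `log2fc`, `statistic`, `p`, `p_adj`
#'   (Benjamini-Hochberg, informational only), `n_in`, `n_out`, `testable`,
#'   `significant`.
#' @export
differential_table <- function(m, labels, target, p_thresh = 0.05,
                               fc_thresh = 1.5, min_frac = 0.3,
                               variant = "student") {
  v <- as_values(m)
  labels <- as.character(labels)
  if (length(labels) != ncol(v)) stop("`labels` must have one entry per sample")
  if (!target %in% labels) stop("target '", target, "' not present in labels")
  if (sum(labels == target) < 3) stop("target group has fewer than 3 samples")
  v <- as_values(filter_validity(v, min_frac, "per_group", groups = labels))
  ix_in <- labels == target
  res <- data.frame(feature = rownames(v), mean_in = NA_real_,
                    mean_out = NA_real_, mean_diff = NA_real_,
                    log2fc = NA_real_, statistic = NA_real_, p = NA_real_,
                    n_in = NA_integer_, n_out = NA_integer_,
                    testable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ix_in]; y <- v[i, !ix_in]
    tt <- t_test_two_group(x, y, variant)
    res$mean_in[i] <- mean(x, na.rm = TRUE)
    res$mean_out[i] <- mean(y, na.rm = TRUE)
    res$n_in[i] <- sum(!is.na(x)); res$n_out[i] <- sum(!is.na(y))
    res$statistic[i] <- tt$statistic; res$p[i] <- tt$p
    res$testable[i] <- tt$testable
  }
  res$mean_diff <- res$mean_in - res$mean_out
  res$log2fc <- res$mean_diff
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- res$testable & !is.na(res$p) & res$p < p_thresh &
    abs(res$log2fc) > fc_thresh
  res
}

#' One-way ANOVA across all subtypes, per feature
#'
#' Classic fixed-effects one-way ANOVA (equal variances) on the observed
#' values of each feature across all groups.
#'
#' @inheritParams differential_table
#' @return data.frame: `feature`, `F`, `p`, `pass` (`p < p_thresh`).
#' @export
anova_across <- function(m, labels, p_thresh = 0.05) {
  v <- as_values(m)
  labels <- as.character(labels)
  if (length(labels) != ncol(v)) stop("`labels` must have one entry per sample")
  out <- data.frame(feature = rownames(v), F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  g <- factor(labels)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    ok <- !is.na(x)
    gi <- droplevels(g[ok])
    if (length(unique(gi)) < 2 || any(table(gi) < 2)) next
    ft <- tryCatch(stats::oneway.test(x[ok] ~ gi, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || is.na(ft$p.value)) next
    out$F[i] <- unname(ft$statistic)
    out$p[i] <- ft$p.value
  }
  out$pass <- !is.na(out$p) & out$p < p_thresh
  out
}

#' Select the top-n biomarker candidates by combined rank
#'
#' Filters a differential table to significant features changed in the
#' requested direction, ranks them by the sum of the p-value rank (ascending)
#' and the mean-difference rank (descending), and returns the first `n`.
#' Ties break by smaller p, then larger mean difference, then feature id.
#'
#' @param records a data.frame from [differential_table()].
#' @param n number of markers to select.
#' @param direction `"up"` (positive mean difference) or `"down"`.
#' @return Character vector of feature ids (shorter than `n`, with a warning,
#'   when fewer qualify). Attribute `"table"` carries the ranked candidates.
#' @export
select_top_markers <- function(records, n = 5, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- records$significant &
    if (direction == "up") records$mean_diff > 0 else records$mean_diff < 0
  cand <- records[keep & !is.na(keep), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no qualifying marker candidates")
    out <- character(0)
    attr(out, "table") <- cand
    return(out)
  }
  eff <- if (direction == "up") cand$mean_diff else -cand$mean_diff
  combined <- rank(cand$p, ties.method = "min") +
    rank(-eff, ties.method = "min")
  o <- order(combined, cand$p, -eff, cand$feature)
  cand <- cand[o, , drop = FALSE]
  cand$combined_rank <- combined[o]
  if (nrow(cand) < n)
    warning("only ", nrow(cand), " qualifying candidates (requested ", n, ")")
  out <- utils::head(cand$feature, n)
  attr(out, "table") <- cand
  out
}
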