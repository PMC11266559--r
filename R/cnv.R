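#' Gene-level genomic signal from protein abundance
#'
#' Maps (row-centered) protein abundances to genes via the gene annotation,
#' averages duplicate proteins of the same gene, and orders genes along the
#' genome. With `unit = "per_group"` the signal is the per-gene group mean
#' over samples, computed only where the gene is observed in at least 30% of
#' the group's samples.
#'
#' @param prot [abundance_matrix()] or matrix of row-centered log2
#'   abundances, UniProt-keyed.
#' @param genes gene annotation data.frame: `gene`, `uniprot`, `chrom`,
#'   `start`, `end`, `arm`.
#' @param unit `"per_sample"` or `"per_group"`.
#' @param labels per-sample group labels (required for `per_group`).
#' @param min_group_frac per-group validity required for a group-mean gene
#'   value.
#' @return A list of class `genomic_signal`: `genes` (ordered annotation of
#'   mapped genes), `values` (genes x units matrix), `n_unmapped` (proteins
#'   without gene mapping).
#' @export
gene_level_signal <- function(prot, genes, unit = c("per_sample", "per_group"),
                              labels = NULL, min_group_frac = 0.3) {
  unit <- match.arg(unit)
  v <- as_values(prot)
  gi <- match(rownames(v), genes$uniprot)
  n_unmapped <- sum(is.na(gi))
  keep <- !is.na(gi)
  v <- v[keep, , drop = FALSE]
  gene_of <- genes$gene[gi[keep]]
  # duplicate proteins of one gene: average
  glev <- unique(gene_of)
  gm <- matrix(NA_real_, length(glev), ncol(v),
               dimnames = list(glev, colnames(v)))
  dup <- glev[vapply(glev, function(g) sum(gene_of == g) > 1, TRUE)]
  single <- setdiff(glev, dup)
  gm[single, ] <- v[match(single, gene_of), , drop = FALSE]
  for (g in dup)
    gm[g, ] <- colMeans(v[gene_of == g, , drop = FALSE], na.rm = TRUE)
  gm[is.nan(gm)] <- NA_real_

  ga <- genes[match(glev, genes$gene), ]
  chrom_rank <- chrom_order(ga$chrom)
  o <- order(chrom_rank, ga$start)
  ga <- ga[o, ]; gm <- gm[o, , drop = FALSE]
  if (nrow(gm) < 50) stop("fewer than 50 mappable genes")

  if (unit == "per_group") {
    if (is.null(labels)) stop("labels required for per_group")
    labels <- as.character(labels)
    groups <- unique(labels)
    out <- matrix(NA_real_, nrow(gm), length(groups),
                  dimnames = list(rownames(gm), groups))
    for (g in groups) {
      ix <- which(labels == g)
      sub <- gm[, ix, drop = FALSE]
      mu <- rowMeans(sub, na.rm = TRUE)
      mu[rowMeans(!is.na(sub)) < min_group_frac] <- NA_real_
      out[, g] <- mu
    }
    gm <- out
  }
  structure(list(genes = ga, values = gm, n_unmapped = n_unmapped),
            class = "genomic_signal")
}

chrom_order <- function(chrom) {
  ch <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.integer(ch))
  rank[ch == "X"] <- 23L
  rank[ch == "Y"] <- 24L
  rank
}

# Welch t statistic between two flanks; Inf when variances vanish but means
# differ (the noiseless piecewise-constant case), 0 when the flanks agree.
welch_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (is.na(v1)) v1 <- 0  # single-marker flank: variance undefined
  if (is.na(v2)) v2 <- 0
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2))
    return(list(t = Inf, df = n1 + n2 - 2))
  }
  df <- se2^2 / ((v1 / n1)^2 / max(n1 - 1, 1) + (v2 / n2)^2 / max(n2 - 1, 1))
  list(t = abs(m1 - m2) / sqrt(se2), df = df)
}

segment_one <- function(x, lo, hi, min_seg_size, alpha) {
  n <- hi - lo + 1
  if (n < 2 * min_seg_size) return(c(lo = lo, hi = hi))
  cand <- (lo + min_seg_size - 1):(hi - min_seg_size)
  best_t <- -1; best_df <- 1; best_b <- NA_integer_
  for (b in cand) {
    ws <- welch_stat(x[lo:b], x[(b + 1):hi])
    if (ws$t > best_t) { best_t <- ws$t; best_df <- ws$df; best_b <- b }
  }
  p <- if (is.infinite(best_t)) 0 else
    2 * stats::pt(-best_t, best_df) * length(cand)  # Bonferroni over candidates
  if (is.na(p) || p >= alpha) return(c(lo = lo, hi = hi))
  rbind(segment_one(x, lo, best_b, min_seg_size, alpha),
        segment_one(x, best_b + 1, hi, min_seg_size, alpha))
}

#' Segment an ordered genomic signal by recursive binary splitting
#'
#' Within each chromosome of each unit, repeatedly places the breakpoint
#' maximizing the two-sided Welch t statistic between the flanks (each at
#' least `min_seg_size` markers), accepts it when the Bonferroni-corrected p
#' value falls below `alpha`, and recurses. Exact on noiseless
#' piecewise-constant input. Missing markers are dropped before
#' segmentation.
#'
#' @param signal a `genomic_signal` from [gene_level_signal()], or a list
#'   with `genes` and `values` of the same shape (e.g. a synthetic methylome
#'   copy-number signal).
#' @param min_seg_size minimum markers per segment.
#' @param alpha split acceptance level after Bonferroni correction.
#' @return data.frame (SEG-style): `unit`, `chrom`, `start`, `end`,
#'   `n_markers`, `seg_mean`, plus `first_marker`/`last_marker` indices into
#'   the per-chromosome marker order and `genes` (comma-joined member genes).
#' @export
segment_signal <- function(signal, min_seg_size = 10, alpha = 0.01) {
  ga <- signal$genes; vals <- signal$values
  out <- list()
  for (u in colnames(vals)) {
    for (ch in unique(ga$chrom)) {
      ix <- which(ga$chrom == ch)
      x <- vals[ix, u]
      ok <- !is.na(x)
      if (!any(ok)) { warning("unit ", u, ": chrom ", ch, " all missing, skipped"); next }
      ix <- ix[ok]; x <- x[ok]
      segs <- if (length(x) < min_seg_size)
        c(lo = 1, hi = length(x))
      else segment_one(x, 1L, length(x), min_seg_size, alpha)
      if (is.null(dim(segs))) segs <- matrix(segs, 1, dimnames = list(NULL, c("lo", "hi")))
      for (s in seq_len(nrow(segs))) {
        lo <- segs[s, "lo"]; hi <- segs[s, "hi"]
        mem <- ix[lo:hi]
        out[[length(out) + 1]] <- data.frame(
          unit = u, chrom = ch, start = ga$start[mem[1]],
          end = ga$end[mem[length(mem)]], n_markers = length(mem),
          seg_mean = mean(x[lo:hi]),
          first_marker = lo, last_marker = hi,
          genes = paste(ga$gene[mem], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Call gain/neutral/loss on segments
#'
#' Inclusive cutoff: gain when `seg_mean >= cutoff`, loss when
#' `seg_mean <= -cutoff`, neutral otherwise.
#'
#' @param segs data.frame from [segment_signal()] or read from SEG.
#' @param cutoff absolute seg-mean threshold (default 0.2).
#' @return The input with an added `state` column.
#' @export
call_segments <- function(segs, cutoff = 0.2) {
  segs$state <- ifelse(segs$seg_mean >= cutoff, "gain",
                       ifelse(segs$seg_mean <= -cutoff, "loss", "neutral"))
  segs
}

# Map each gene to the state of the segment containing it; then majority
# state over a bin's genes decides the sample's call for that bin.
gene_states <- function(calls, genes) {
  st <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene)
  rows <- calls[calls$n_markers >= 1, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    mem <- strsplit(rows$genes[i], ",", fixed = TRUE)[[1]]
    st[mem] <- rows$state[i]
  }
  st
}

#' Group-level gain/loss frequency profile per genomic bin
#'
#' For each group and chromosome-arm bin, the percentage of samples whose
#' call on that bin (majority state over the bin's markers) is gain,
#' respectively loss. Each sample contributes at most once per bin.
#'
#' @param calls per-sample called segments (from [call_segments()], unit =
#'   sample ids).
#' @param genes gene annotation (supplies the arm of each marker).
#' @param labels named or ordered group labels for the sample units.
#' @return data.frame: `group`, `bin`, `gain_pct`, `loss_pct`, `n_samples`.
#' @export
frequency_profile <- function(calls, genes, labels) {
  units <- unique(calls$unit)
  if (is.null(names(labels))) names(labels) <- units
  arms <- unique(genes$arm[order(chrom_order(genes$chrom), genes$start)])
  groups <- unique(as.character(labels[units]))
  res <- list()
  state_by_unit <- lapply(units, function(u)
    gene_states(calls[calls$unit == u, , drop = FALSE], genes))
  names(state_by_unit) <- units
  arm_of <- stats::setNames(genes$arm, genes$gene)
  for (g in groups) {
    us <- units[as.character(labels[units]) == g]
    for (a in arms) {
      gset <- genes$gene[genes$arm == a]
      gain <- 0L; loss <- 0L
      for (u in us) {
        st <- state_by_unit[[u]][gset]
        st <- st[!is.na(st)]
        if (length(st) == 0) next
        tb <- table(st)
        call <- names(tb)[which.max(tb)]
        if (call == "gain") gain <- gain + 1L
        if (call == "loss") loss <- loss + 1L
      }
      res[[length(res) + 1]] <- data.frame(
        group = g, bin = a, gain_pct = 100 * gain / length(us),
        loss_pct = 100 * loss / length(us), n_samples = length(us),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Arm-level cross-platform correlation of copy-number profiles
#'
#' Builds per-group arm-level mean seg-mean vectors (marker-weighted) for
#' two platforms and correlates them across arms (Pearson, pairwise
#' complete).
#'
#' @param prot_segs,meth_segs called or raw segment tables whose units are
#'   samples.
#' @param genes gene annotation shared by both platforms.
#' @param labels group labels for the sample units (named by sample).
#' @return data.frame: `group`, `r`, `n_arms`.
#' @export
cross_platform_correlation <- function(prot_segs, meth_segs, genes, labels) {
  arm_means <- function(segs) {
    units <- unique(segs$unit)
    arms <- unique(genes$arm)
    arm_of <- stats::setNames(genes$arm, genes$gene)
    m <- matrix(NA_real_, length(arms), length(units),
                dimnames = list(arms, units))
    for (u in units) {
      rows <- segs[segs$unit == u, , drop = FALSE]
      vals <- list()
      for (i in seq_len(nrow(rows))) {
        mem <- strsplit(rows$genes[i], ",", fixed = TRUE)[[1]]
        for (a in unique(arm_of[mem])) {
          vals[[a]] <- c(vals[[a]], rep(rows$seg_mean[i], sum(arm_of[mem] == a)))
        }
      }
      for (a in names(vals)) m[a, u] <- mean(vals[[a]])
    }
    m
  }
  mp <- arm_means(prot_segs)
  mm <- arm_means(meth_segs)
  units <- intersect(colnames(mp), colnames(mm))
  groups <- unique(as.character(labels[units]))
  out <- list()
  for (g in groups) {
    us <- units[as.character(labels[units]) == g]
    vp <- rowMeans(mp[, us, drop = FALSE], na.rm = TRUE)
    vm <- rowMeans(mm[rownames(mp), us, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(vp) & is.finite(vm)
    r <- if (sum(ok) >= 3 && stats::sd(vp[ok]) > 0 && stats::sd(vm[ok]) > 0)
      stats::cor(vp[ok], vm[ok]) else NA_real_
    if (is.na(r)) warning("group ", g, ": cross-platform r undefined")
    out[[length(out) + 1]] <- data.frame(group = g, r = r, n_arms = sum(ok),
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
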