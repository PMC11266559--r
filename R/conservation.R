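#' Beta-value / M-value conversions
#'
#' `M = log2(beta / (1 - beta))`, the log2 ratio of methylated to
#' unmethylated signal. Beta values are clamped to `[eps, 1 - eps]` before
#' the transform so boundary values stay finite.
#'
#' @param beta,m numeric vectors or matrices.
#' @param eps clamping constant.
#' @return The transformed values; the round trip is an identity to 1e-9 for
#'   beta in `(eps, 1 - eps)`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  b <- 2^m
  b / (1 + b)
}

#' Drop flagged and sex-chromosome probes
#'
#' @param meth probes x samples M-value matrix.
#' @param annot probe annotation data.frame (`probe_id`, `chrom`,
#'   `quality_flag`, `snp_flag`).
#' @param drop_flags subset of `c("quality", "snp", "sex_chrom")`.
#' @return Filtered matrix; attribute `"n_removed"` gives per-rule counts.
#' @export
filter_probes <- function(meth, annot,
                          drop_flags = c("quality", "snp", "sex_chrom")) {
  ai <- match(rownames(meth), annot$probe_id)
  if (anyNA(ai)) stop("probes missing from annotation: ",
                      paste(utils::head(rownames(meth)[is.na(ai)]), collapse = ", "))
  a <- annot[ai, ]
  drop <- rep(FALSE, nrow(meth))
  n_removed <- c(quality = 0L, snp = 0L, sex_chrom = 0L)
  if ("quality" %in% drop_flags) {
    n_removed["quality"] <- sum(a$quality_flag & !drop)
    drop <- drop | a$quality_flag
  }
  if ("snp" %in% drop_flags) {
    n_removed["snp"] <- sum(a$snp_flag & !drop)
    drop <- drop | a$snp_flag
  }
  if ("sex_chrom" %in% drop_flags) {
    sex <- a$chrom %in% c("X", "Y", "chrX", "chrY")
    n_removed["sex_chrom"] <- sum(sex & !drop)
    drop <- drop | sex
  }
  out <- meth[!drop, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' Subtype-restricted protein/CpG Pearson correlation
#'
#' Correlates protein abundance with CpG M-values over the pairwise-complete
#' samples of one subtype. Pairs are either all protein x CpG combinations or
#' only own-gene pairs (protein's gene appears in the probe's gene
#' annotation, case-insensitive). A record passes at `r > r_thresh` (signed,
#' default) or `|r| > r_thresh` (`use_abs = TRUE`).
#'
#' @param prot [abundance_matrix()] or matrix, proteins x samples.
#' @param meth probes x samples M-value matrix (shared sample ids).
#' @param labels per-sample subtype labels (named or in column order of
#'   `prot`).
#' @param subtype the subtype whose samples are used.
#' @param pairs `"own_gene_only"` or `"all"`.
#' @param gene_annot required for `own_gene_only`: data.frame mapping
#'   `uniprot` to `gene`.
#' @param probe_annot probe annotation with `probe_id` and `gene` (possibly
#'   `;`-separated multi-gene strings).
#' @param r_thresh pass cutoff.
#' @param use_abs use `|r|` instead of signed r.
#' @param min_overlap minimum shared observed samples for r to be defined.
#' @return data.frame of `CorrelationRecord`s: `protein`, `cpg`, `gene`,
#'   `subtype`, `r`, `n_overlap`, `own_gene`, `passes`.
#' @export
subtype_correlation <- function(prot, meth, labels, subtype,
                                pairs = c("own_gene_only", "all"),
                                gene_annot = NULL, probe_annot = NULL,
                                r_thresh = 0.7, use_abs = FALSE,
                                min_overlap = 5) {
  pairs <- match.arg(pairs)
  v <- as_values(prot)
  labels <- as.character(labels)
  if (length(labels) != ncol(v)) stop("`labels` must have one entry per sample")
  cols <- which(labels == as.character(subtype))
  if (length(cols) < min_overlap)
    stop("subtype '", subtype, "' has fewer than min_overlap samples")
  common <- intersect(colnames(v), colnames(meth))
  cols <- intersect(colnames(v)[cols], common)
  vp <- v[, cols, drop = FALSE]
  vm <- meth[, cols, drop = FALSE]

  prot_gene <- NULL
  probe_genes <- NULL
  if (!is.null(gene_annot))
    prot_gene <- stats::setNames(toupper(gene_annot$gene), gene_annot$uniprot)
  if (!is.null(probe_annot))
    probe_genes <- stats::setNames(toupper(probe_annot$gene), probe_annot$probe_id)

  if (pairs == "own_gene_only") {
    if (is.null(gene_annot) || is.null(probe_annot))
      stop("own_gene_only requires gene_annot and probe_annot")
    # explode multi-gene probe annotations and match by symbol
    pg <- strsplit(probe_genes[rownames(vm)], ";", fixed = TRUE)
    pair_list <- list()
    gene_of_prot <- prot_gene[rownames(vp)]
    prot_by_gene <- split(rownames(vp), gene_of_prot)
    for (i in seq_along(pg)) {
      gs <- pg[[i]]
      if (length(gs) == 0 || all(is.na(gs))) next
      prots <- unique(unlist(prot_by_gene[gs], use.names = FALSE))
      if (length(prots))
        pair_list[[length(pair_list) + 1]] <-
          data.frame(protein = prots, cpg = rownames(vm)[i],
                     stringsAsFactors = FALSE)
    }
    if (length(pair_list) == 0)
      return(empty_correlation_records())
    pairs_df <- do.call(rbind, pair_list)
  } else {
    pairs_df <- expand.grid(protein = rownames(vp), cpg = rownames(vm),
                            stringsAsFactors = FALSE)
  }

  r <- numeric(nrow(pairs_df)); n_ov <- integer(nrow(pairs_df))
  for (i in seq_len(nrow(pairs_df))) {
    x <- vp[pairs_df$protein[i], ]; y <- vm[pairs_df$cpg[i], ]
    ok <- !is.na(x) & !is.na(y)
    n_ov[i] <- sum(ok)
    r[i] <- if (n_ov[i] >= min_overlap && stats::sd(x[ok]) > 0 &&
                stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok]) else NA_real_
  }
  own <- if (!is.null(prot_gene) && !is.null(probe_genes)) {
    mapply(function(pr, cg) {
      g <- prot_gene[[pr]]
      !is.na(g) && g %in% strsplit(probe_genes[[cg]] %||% NA_character_,
                                   ";", fixed = TRUE)[[1]]
    }, pairs_df$protein, pairs_df$cpg)
  } else rep(NA, nrow(pairs_df))
  crit <- if (use_abs) abs(r) else r
  data.frame(protein = pairs_df$protein, cpg = pairs_df$cpg,
             gene = if (!is.null(prot_gene)) unname(prot_gene[pairs_df$protein])
                    else NA_character_,
             subtype = as.character(subtype), r = r, n_overlap = n_ov,
             own_gene = own,
             passes = !is.na(r) & crit > r_thresh,
             stringsAsFactors = FALSE)
}

empty_correlation_records <- function() {
  data.frame(protein = character(0), cpg = character(0), gene = character(0),
             subtype = character(0), r = numeric(0), n_overlap = integer(0),
             own_gene = logical(0), passes = logical(0))
}

#' Fraction of proteins conserved with their own gene's methylation
#'
#' Percent of proteins in the universe with at least one passing own-gene
#' correlation record.
#'
#' @param records data.frame from [subtype_correlation()].
#' @param universe character vector of protein ids forming the denominator.
#' @return A list: `percent`, `count`, `n_universe`.
#' @export
conservation_fraction <- function(records, universe) {
  hit <- unique(records$protein[records$passes & records$own_gene %in% TRUE])
  hit <- intersect(hit, universe)
  list(percent = 100 * length(hit) / length(universe),
       count = length(hit), n_universe = length(universe))
}

#' Positional distribution of passing own-gene CpGs
#'
#' Proportion of passing own-gene correlation records per probe feature
#' class, plus the aggregate share at the transcription start site
#' (TSS200 + TSS1500 + 1stExon).
#'
#' @param records data.frame from [subtype_correlation()].
#' @param probe_annot probe annotation with `probe_id`, `feature_class`.
#' @return Named numeric vector of proportions (summing to 1) with attribute
#'   `"tss_aggregate"`.
#' @export
position_distribution <- function(records, probe_annot) {
  keep <- records$passes & records$own_gene %in% TRUE
  if (!any(keep)) stop("no passing own-gene records; no distribution defined")
  fc <- probe_annot$feature_class[match(records$cpg[keep], probe_annot$probe_id)]
  tab <- table(fc)
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  attr(prop, "tss_aggregate") <-
    sum(prop[names(prop) %in% c("TSS200", "TSS1500", "1stExon")])
  prop
}

#' Validate a DMR table against the probe-run rules
#'
#' Each differentially methylated region must contain at least `min_probes`
#' member probes, sorted by position, with consecutive gaps below `max_gap`
#' nucleotides.
#'
#' @param dmrs list of DMRs, each a list with `dmr_id`, `chrom`, `start`,
#'   `end`, `probes` (character vector), or a data.frame in long format
#'   (`dmr_id`, `chrom`, `probe_id`, `pos`).
#' @param probe_annot probe annotation supplying positions.
#' @param min_probes,max_gap the rules (defaults 10 probes, < 1000 nt gaps).
#' @return Invisibly, the normalized list of DMRs; errors on violation.
#' @export
validate_dmr_table <- function(dmrs, probe_annot, min_probes = 10,
                               max_gap = 1000) {
  if (is.data.frame(dmrs)) {
    dmrs <- lapply(split(dmrs, dmrs$dmr_id), function(d)
      list(dmr_id = d$dmr_id[1], chrom = d$chrom[1],
           probes = d$probe_id))
  }
  pos <- stats::setNames(probe_annot$pos, probe_annot$probe_id)
  for (d in dmrs) {
    p <- pos[d$probes]
    if (anyNA(p)) stop("DMR ", d$dmr_id, ": unknown probe(s)")
    if (length(p) < min_probes)
      stop("DMR ", d$dmr_id, ": fewer than ", min_probes, " probes")
    if (is.unsorted(p))
      stop("DMR ", d$dmr_id, ": member probes not sorted by position")
    if (length(p) > 1 && any(diff(p) >= max_gap))
      stop("DMR ", d$dmr_id, ": consecutive probe gap >= ", max_gap, " nt")
  }
  invisible(dmrs)
}

#' Aggregate CpG M-values into DMR-level rows
#'
#' Per-sample mean M-value over each DMR's member probes (observed values
#' only). The resulting matrix can be fed back into [subtype_correlation()]
#' for DMR-protein correlation.
#'
#' @inheritParams validate_dmr_table
#' @param meth probes x samples M-value matrix.
#' @return DMR x samples matrix.
#' @export
aggregate_dmr <- function(meth, dmrs, probe_annot, min_probes = 10,
                          max_gap = 1000) {
  dmrs <- validate_dmr_table(dmrs, probe_annot, min_probes, max_gap)
  out <- t(vapply(dmrs, function(d)
    colMeans(meth[d$probes, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(meth))))
  rownames(out) <- vapply(dmrs, function(d) as.character(d$dmr_id), "")
  colnames(out) <- colnames(meth)
  out
}

#' Per-gene three-omic pairwise correlation
#'
#' For each gene in a set, Pearson correlation between its protein
#' abundance, transcript abundance and (mean own-gene) CpG methylation over
#' matched samples; reports which genes pass on all three pairings at
#' `|r| >= r_thresh` or signed `r >= r_thresh`.
#'
#' @param prot,rna matrices keyed by gene-level feature ids; `meth` is a gene
#'   x samples matrix (e.g. own-gene probe means or DMR rows mapped to
#'   genes).
#' @param genes character vector of gene-level row ids present in all three.
#' @param r_thresh pass cutoff (inclusive).
#' @param use_abs compare `|r|` (default) or signed r.
#' @param min_overlap minimum matched samples per pairing.
#' @return data.frame: `gene`, `r_prot_rna`, `r_rna_cpg`, `r_prot_cpg`,
#'   per-pair pass flags and `passes_all`.
#' @export
triomics_correlation <- function(prot, rna, meth, genes, r_thresh = 0.7,
                                 use_abs = TRUE, min_overlap = 5) {
  vp <- as_values(prot)
  common <- Reduce(intersect, list(colnames(vp), colnames(rna), colnames(meth)))
  if (length(common) < 2) stop("fewer than 2 matched samples across the three matrices")
  pair_r <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_overlap || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  out <- data.frame(gene = genes, r_prot_rna = NA_real_, r_rna_cpg = NA_real_,
                    r_prot_cpg = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (!g %in% rownames(vp) || !g %in% rownames(rna) || !g %in% rownames(meth))
      next
    out$r_prot_rna[i] <- pair_r(vp[g, common], rna[g, common])
    out$r_rna_cpg[i] <- pair_r(rna[g, common], meth[g, common])
    out$r_prot_cpg[i] <- pair_r(vp[g, common], meth[g, common])
  }
  crit <- function(r) {
    v <- if (use_abs) abs(r) else r
    !is.na(r) & v >= r_thresh
  }
  out$pass_prot_rna <- crit(out$r_prot_rna)
  out$pass_rna_cpg <- crit(out$r_rna_cpg)
  out$pass_prot_cpg <- crit(out$r_prot_cpg)
  out$passes_all <- out$pass_prot_rna & out$pass_rna_cpg & out$pass_prot_cpg
  out
}
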