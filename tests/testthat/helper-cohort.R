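# Shared fixture builders. Cohorts are cached per configuration digest so
# repeated tests do not regenerate them.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(cfg) {
  key <- paste(deparse(unclass(cfg)), collapse = "")
  key <- paste0("c", sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 1e9,
                "_", cfg$seed)
  if (!exists(key, .cohort_cache))
    assign(key, simulate_cohort(cfg), .cohort_cache)
  get(key, .cohort_cache)
}

# Reference synthetic cohort of the subtype-recovery experiments.
reference_config <- function(seed = 1, batch_location_sd = 1) {
  cohort_config(n_samples = 120, n_proteins = 1500, n_cpgs = 2000,
                k_subtypes = 6, n_markers_per_subtype = 60,
                marker_shift = 1.5, noise_sd = 1, n_batches = 4,
                batch_location_sd = batch_location_sd, missing_frac = 0.25,
                missing_mode = "MCAR", seed = seed)
}

# Standard harmonization chain used ahead of clustering / CNV.
harmonize_chain <- function(prot, mode = "location") {
  row_mean_center(dissect_and_adjust_batches(median_normalize_columns(prot),
                                             mode))
}

# Fast per-row variance explained by batch, averaged over rows.
mean_batch_r2 <- function(m, batch) {
  v <- if (inherits(m, "abundance_matrix")) m$values else m
  g <- factor(batch)
  r2 <- apply(v, 1, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 8) return(NA_real_)
    x <- x[ok]; gi <- droplevels(g[ok])
    if (nlevels(gi) < 2) return(NA_real_)
    mb <- tapply(x, gi, mean); nb <- tabulate(gi)
    ssb <- sum(nb * (mb - mean(x))^2)
    sst <- sum((x - mean(x))^2)
    if (sst == 0) return(NA_real_)
    ssb / sst
  })
  mean(r2, na.rm = TRUE)
}

# Tiny labelled matrix helper for contract examples.
toy_matrix <- function(values, nrow, byrow = TRUE, prefix = "P") {
  m <- matrix(values, nrow = nrow, byrow = byrow)
  rownames(m) <- paste0(prefix, seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}
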