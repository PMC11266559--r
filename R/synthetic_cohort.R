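#' Configuration for the synthetic multiomic cohort generator
#'
#' Defines the generative conditions for [simulate_cohort()]: planted proteome
#' subtypes with marker panels, TMT-style batch location/scale effects,
#' missing values (MCAR or intensity-dependent), subtype-restricted
#' protein/CpG coupling, arm-level copy-number events propagating attenuated
#' into protein abundance, and blood-contaminated samples.
#'
#' @param n_samples,n_proteins,n_cpgs cohort dimensions.
#' @param k_subtypes number of planted subtypes (>= 2).
#' @param subtype_proportions probability vector of length `k_subtypes`
#'   (default equal); must sum to 1.
#' @param n_markers_per_subtype markers planted per subtype;
#'   `k_subtypes * n_markers_per_subtype` must not exceed `n_proteins`.
#' @param marker_shift abundance shift of a subtype's markers in its own
#'   samples, log2 units.
#' @param noise_sd residual noise standard deviation, log2 units.
#' @param n_batches number of TMT-like batches (samples assigned at random,
#'   balanced).
#' @param batch_location_sd sd of per-protein-per-batch additive offsets,
#'   log2 units.
#' @param batch_scale_range interval from which per-protein-per-batch
#'   multiplicative noise-scale factors are drawn; `c(1, 1)` disables scale
#'   effects.
#' @param missing_frac target fraction of missing entries in the proteome.
#' @param missing_mode `"MCAR"` or `"intensity"` (logistic missingness in the
#'   latent abundance, MNAR, emulating low-abundance dropout).
#' @param coupling_frac fraction of proteins per subtype coupled to one CpG of
#'   their own gene; scalar or vector of length `k_subtypes`.
#' @param coupling_rho target within-subtype Pearson correlation of coupled
#'   pairs (verified post hoc to +-0.1 and regenerated if violated).
#' @param cnv_events list of [cnv_event()] specifications.
#' @param n_contaminated number of blood-contaminated samples.
#' @param blood_panel_size number of proteins in the blood panel.
#' @param contamination_shift uniform elevation of blood-panel proteins in
#'   contaminated samples, log2 units.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 120, n_proteins = 1500, n_cpgs = 2000,
                          k_subtypes = 6,
                          subtype_proportions = rep(1 / k_subtypes, k_subtypes),
                          n_markers_per_subtype = 60, marker_shift = 1.5,
                          noise_sd = 1, n_batches = 4, batch_location_sd = 1,
                          batch_scale_range = c(1, 1),
                          missing_frac = 0.25,
                          missing_mode = c("MCAR", "intensity"),
                          coupling_frac = 0, coupling_rho = 0.9,
                          cnv_events = list(),
                          n_contaminated = 0, blood_panel_size = 30,
                          contamination_shift = 4,
                          seed = 1) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_samples = n_samples, n_proteins = n_proteins, n_cpgs = n_cpgs,
              k_subtypes = k_subtypes, subtype_proportions = subtype_proportions,
              n_markers_per_subtype = n_markers_per_subtype,
              marker_shift = marker_shift, noise_sd = noise_sd,
              n_batches = n_batches, batch_location_sd = batch_location_sd,
              batch_scale_range = batch_scale_range,
              missing_frac = missing_frac, missing_mode = missing_mode,
              coupling_frac = coupling_frac, coupling_rho = coupling_rho,
              cnv_events = cnv_events, n_contaminated = n_contaminated,
              blood_panel_size = blood_panel_size,
              contamination_shift = contamination_shift, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (k_subtypes < 2) stop("k_subtypes must be >= 2")
    if (abs(sum(subtype_proportions) - 1) > 1e-9)
      stop("subtype_proportions must sum to 1")
    if (length(subtype_proportions) != k_subtypes)
      stop("subtype_proportions must have length k_subtypes")
    if (n_markers_per_subtype * k_subtypes > n_proteins)
      stop("infeasible config: k_subtypes * n_markers_per_subtype (",
           n_markers_per_subtype * k_subtypes, ") exceeds n_proteins (",
           n_proteins, ")")
    fr <- c(missing_frac, coupling_frac)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (abs(coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
    if (length(batch_scale_range) != 2 || any(batch_scale_range <= 0) ||
        diff(batch_scale_range) < 0)
      stop("batch_scale_range must be a positive non-decreasing interval")
    if (n_contaminated > n_samples) stop("n_contaminated exceeds n_samples")
    for (e in cnv_events) validate_cnv_event(e)
  })
  invisible(cfg)
}

#' Specify a planted arm-level copy-number event
#'
#' @param arm chromosome arm, e.g. `"7p"`.
#' @param direction `"gain"` or `"loss"`.
#' @param logratio magnitude of the event on the methylome copy-number scale
#'   (log2 ratio), positive.
#' @param subtype 1-based index of the carrier subtype.
#' @param carrier_frac fraction of that subtype's samples carrying the event.
#' @param attenuation multiplicative factor with which the event propagates
#'   into protein abundance (proteome effect = `logratio * attenuation`).
#' @return A list of class `cnv_event`.
#' @export
cnv_event <- function(arm, direction = c("gain", "loss"), logratio = 0.3,
                      subtype = 1, carrier_frac = 1, attenuation = 0.5) {
  direction <- match.arg(direction)
  structure(list(arm = arm, direction = direction, logratio = logratio,
                 subtype = subtype, carrier_frac = carrier_frac,
                 attenuation = attenuation), class = "cnv_event")
}

validate_cnv_event <- function(e) {
  if (!inherits(e, "cnv_event")) stop("cnv_events entries must be cnv_event()")
  if (e$logratio <= 0) stop("cnv_event logratio must be positive")
  if (e$carrier_frac < 0 || e$carrier_frac > 1) stop("carrier_frac in [0,1]")
  invisible(e)
}

# Simplified diploid genome: autosomes 1-22 plus X/Y, 200 Mb each, centromere
# at 100 Mb splitting p from q. No centromere model beyond the arm boundary.
synthetic_genome <- function() {
  chroms <- c(as.character(1:22), "X", "Y")
  data.frame(chrom = chroms, length = 2e8, centromere = 1e8,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multiomic cohort with known ground truth
#'
#' Draws a proteome abundance matrix (baseline + subtype marker shifts +
#' batch location/scale effects + attenuated copy-number shifts + noise,
#' masked to the target missingness), a CpG M-value matrix with
#' subtype-restricted coupling to proteins of the same gene, probe and gene
#' annotation, a gene-level methylome copy-number log-ratio matrix, and the
#' complete ground truth.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `prot` ([abundance_matrix()] with batch
#'   labels), `meth` (probes x samples M-value matrix), `probe_annot`
#'   (data.frame: probe_id, chrom, pos, strand, gene, feature_class,
#'   quality_flag, snp_flag), `gene_annot` (data.frame: gene, uniprot, chrom,
#'   start, end, arm), `meth_cnv` (genes x samples copy-number log-ratio
#'   matrix), and `truth` (subtype, batch, markers, coupled pairs, CNV
#'   carriers, contaminated samples, blood panel).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_proteins; k <- config$k_subtypes

  sample_ids <- sprintf("S%03d", seq_len(n))
  prot_ids <- sprintf("P%05d", seq_len(p))
  genes <- sprintf("GENE%05d", seq_len(p))

  ## genome & gene annotation: one gene per protein, uniform coordinates
  gen <- synthetic_genome()
  chrom <- sample(gen$chrom, p, replace = TRUE)
  start <- floor(stats::runif(p, 1, 2e8 - 2e4))
  gene_annot <- data.frame(gene = genes, uniprot = prot_ids, chrom = chrom,
                           start = start, end = start + 1e4,
                           arm = paste0(chrom, ifelse(start < 1e8, "p", "q")),
                           stringsAsFactors = FALSE)

  ## subtype + batch assignment
  subtype <- sample(rep(seq_len(k), times = round_proportions(config$subtype_proportions, n)))
  names(subtype) <- sample_ids
  batch <- sample(rep(seq_len(config$n_batches), length.out = n))
  batch <- paste0("B", batch)
  names(batch) <- sample_ids

  ## marker panels: disjoint blocks at the head of the protein list
  markers <- split(prot_ids[seq_len(k * config$n_markers_per_subtype)],
                   rep(seq_len(k), each = config$n_markers_per_subtype))
  names(markers) <- paste0("subtype", seq_len(k))

  ## latent abundance
  mu <- stats::rnorm(p, 0, 1)
  signal <- matrix(mu, p, n, dimnames = list(prot_ids, sample_ids))
  for (s in seq_len(k)) {
    cols <- which(subtype == s)
    signal[markers[[s]], cols] <- signal[markers[[s]], cols] + config$marker_shift
  }

  ## CNV events: attenuated shift on genes of the event arm in carriers
  cnv_truth <- list()
  for (e in config$cnv_events) {
    rows <- which(gene_annot$arm == e$arm)
    in_sub <- which(subtype == e$subtype)
    n_car <- round(e$carrier_frac * length(in_sub))
    carriers <- sort(sample(in_sub, n_car))
    sgn <- if (e$direction == "gain") 1 else -1
    signal[rows, carriers] <- signal[rows, carriers] +
      sgn * e$logratio * e$attenuation
    cnv_truth[[length(cnv_truth) + 1]] <-
      c(e, list(carriers = sample_ids[carriers], genes = gene_annot$gene[rows]))
  }

  ## blood contamination: uniform elevation of a designated panel
  contaminated <- character(0); blood_panel <- character(0)
  if (config$n_contaminated > 0) {
    non_marker <- setdiff(prot_ids, unlist(markers))
    blood_panel <- sort(sample(non_marker, config$blood_panel_size))
    contaminated <- sort(sample(sample_ids, config$n_contaminated))
    signal[blood_panel, contaminated] <- signal[blood_panel, contaminated] +
      config$contamination_shift
  }

  ## batch effects + noise
  eps <- matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
  gamma <- matrix(stats::rnorm(p * config$n_batches, 0, config$batch_location_sd),
                  p, config$n_batches)
  delta <- matrix(stats::runif(p * config$n_batches,
                               config$batch_scale_range[1],
                               config$batch_scale_range[2]),
                  p, config$n_batches)
  b_idx <- as.integer(sub("^B", "", batch))
  bio <- signal + eps                     # biology, before measurement artifacts
  latent <- signal + gamma[, b_idx] + delta[, b_idx] * eps

  ## missingness
  values <- latent
  if (config$missing_frac > 0) {
    if (config$missing_mode == "MCAR") {
      mask <- matrix(stats::runif(p * n) < config$missing_frac, p, n)
    } else {
      sc <- 0.5 * max(config$noise_sd, 0.1)
      f <- function(t) mean(stats::plogis((t - latent) / sc)) - config$missing_frac
      t0 <- stats::uniroot(f, range(latent) + c(-5, 5))$root
      mask <- matrix(stats::runif(p * n) < stats::plogis((t0 - latent) / sc), p, n)
    }
    values[mask] <- NA_real_
  }

  ## methylation: background probes + coupled probes
  n_cpg <- config$n_cpgs
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpg))
  cfrac <- rep_len(config$coupling_frac, k)
  coupled <- NULL
  feat_classes <- c("TSS200", "TSS1500", "1stExon", "Body", "3'UTR", "IGR")
  feat_w <- c(0.10, 0.10, 0.05, 0.45, 0.10, 0.20)
  probe_gene <- sample(c(genes, NA_character_), n_cpg, replace = TRUE)
  probe_class <- sample(c(feat_classes, "5'UTR"), n_cpg, replace = TRUE,
                        prob = c(feat_w, 0.05))
  probe_class[is.na(probe_gene)] <- "IGR"

  probe_mu <- stats::rnorm(n_cpg, 0, 2)
  meth <- matrix(stats::rnorm(n_cpg * n, 0, 1), n_cpg, n,
                 dimnames = list(cpg_ids, sample_ids)) + probe_mu
  next_cpg <- 1L
  coupled_rows <- list()
  for (s in seq_len(k)) {
    n_cp <- round(cfrac[s] * p)
    if (n_cp == 0) next
    prot_cp <- sample(prot_ids, n_cp)
    cols <- which(subtype == s)
    for (pr in prot_cp) {
      if (next_cpg > n_cpg)
        stop("n_cpgs too small for the requested coupling fractions")
      cg <- cpg_ids[next_cpg]; next_cpg <- next_cpg + 1L
      # couple against the biological abundance: methylation tracks biology,
      # not TMT batch artifacts (which harmonization later removes)
      zp <- bio[pr, cols]
      zp <- (zp - mean(zp)) / stats::sd(zp)
      rho <- config$coupling_rho
      r_ok <- FALSE
      for (try in 1:100) {
        zc <- rho * zp + sqrt(1 - rho^2) * stats::rnorm(length(cols))
        r <- stats::cor(bio[pr, cols], zc)
        if (abs(r - rho) <= 0.1) { r_ok <- TRUE; break }
      }
      if (!r_ok) stop("could not attain coupling_rho for ", pr)
      meth[cg, cols] <- probe_mu[next_cpg - 1L] + zc
      probe_gene[next_cpg - 1L] <- gene_annot$gene[match(pr, gene_annot$uniprot)]
      probe_class[next_cpg - 1L] <- sample(feat_classes, 1, prob = feat_w)
      coupled_rows[[length(coupled_rows) + 1]] <-
        data.frame(protein = pr, cpg = cg, subtype = s, rho = rho,
                   realized_r = r, stringsAsFactors = FALSE)
    }
  }
  coupled <- if (length(coupled_rows)) do.call(rbind, coupled_rows) else
    data.frame(protein = character(0), cpg = character(0),
               subtype = integer(0), rho = numeric(0), realized_r = numeric(0))

  ## probe annotation; probes inherit their gene's locus (or a random one)
  gi <- match(probe_gene, gene_annot$gene)
  rand_chrom <- sample(gen$chrom, n_cpg, replace = TRUE)
  rand_pos <- floor(stats::runif(n_cpg, 1, 2e8))
  probe_annot <- data.frame(
    probe_id = cpg_ids,
    chrom = ifelse(is.na(gi), rand_chrom, gene_annot$chrom[gi]),
    pos = ifelse(is.na(gi), rand_pos,
                 gene_annot$start[gi] + floor(stats::runif(n_cpg, 0, 1e4))),
    strand = sample(c("+", "-"), n_cpg, replace = TRUE),
    gene = probe_gene,
    feature_class = probe_class,
    quality_flag = stats::runif(n_cpg) < 0.01,
    snp_flag = stats::runif(n_cpg) < 0.02,
    stringsAsFactors = FALSE)

  ## methylome copy-number log-ratio signal (gene level)
  meth_cnv <- matrix(stats::rnorm(p * n, 0, 0.05), p, n,
                     dimnames = list(genes, sample_ids))
  for (ct in cnv_truth) {
    sgn <- if (ct$direction == "gain") 1 else -1
    meth_cnv[ct$genes, ct$carriers] <- meth_cnv[ct$genes, ct$carriers] +
      sgn * ct$logratio
  }

  truth <- list(subtype = subtype, batch = batch, markers = markers,
                coupled = coupled, cnv_events = cnv_truth,
                contaminated = contaminated, blood_panel = blood_panel)
  list(prot = abundance_matrix(values, batch = batch),
       meth = meth, probe_annot = probe_annot, gene_annot = gene_annot,
       meth_cnv = meth_cnv, truth = truth)
}

# Largest-remainder apportionment of n samples to proportions.
round_proportions <- function(prop, n) {
  raw <- prop * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
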