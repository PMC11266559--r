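#' Run the full synthetic multiomic analysis pipeline
#'
#' Orchestrates simulate -> harmonize -> cluster -> markers -> conserve ->
#' cnv -> glycan -> dhscore in dependency order, skipping disabled stages,
#' and writes per-stage outputs plus a manifest (parameters, content hashes,
#' output paths) under `out_dir`. Identical config and seed give identical
#' stage outputs and manifests (modulo the timestamp field).
#'
#' @param config nested list of stage blocks; any subset of `simulate`,
#'   `harmonize`, `cluster`, `markers`, `conserve`, `cnv`, `glycan`,
#'   `dhscore`. Each block is a list of that stage's parameters, or `TRUE`
#'   for defaults. Stages absent (or `FALSE`) are skipped. `config$seed`
#'   seeds every stochastic stage.
#' @param out_dir output directory (created).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("medullomix_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stage_on <- function(s) !is.null(config[[s]]) && !isFALSE(config[[s]])
  block <- function(s) if (is.list(config[[s]])) config[[s]] else list()
  manifest <- list(seed = seed, timestamp = format(Sys.time()), stages = list())
  add_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      params = params,
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))))
  }
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  cohort <- NULL; harmonized <- NULL; labels <- NULL

  if (stage_on("simulate")) {
    tryCatch({
      b <- block("simulate")
      cfg <- do.call(cohort_config, utils::modifyList(list(seed = seed), b))
      cohort <- simulate_cohort(cfg)
      f1 <- file.path(out_dir, "abundance.tsv")
      f2 <- file.path(out_dir, "methylation.tsv")
      f3 <- file.path(out_dir, "probe_annotation.tsv")
      f4 <- file.path(out_dir, "genes.bed")
      f5 <- file.path(out_dir, "truth.json")
      write_matrix_tsv(cohort$prot, f1)
      write_matrix_tsv(cohort$meth, f2)
      utils::write.table(cohort$probe_annot, f3, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_gene_bed(cohort$gene_annot, f4)
      jsonlite::write_json(list(subtype = as.list(cohort$truth$subtype),
                                batch = as.list(cohort$truth$batch),
                                markers = cohort$truth$markers),
                           f5, auto_unbox = TRUE)
      add_stage("simulate", cfg[names(cfg) != "cnv_events"],
                c(f1, f2, f3, f4, f5))
    }, error = function(e) fail("simulate", e))
  }

  if (stage_on("harmonize")) {
    tryCatch({
      if (is.null(cohort)) stop("harmonize requires the simulate stage")
      b <- block("harmonize")
      mode <- b$mode %||% "location"
      min_frac <- b$min_frac %||% 0.3
      m <- median_normalize_columns(cohort$prot)
      m <- dissect_and_adjust_batches(m, mode = mode)
      m <- row_mean_center(m)
      m <- filter_validity(m, min_frac, "global")
      harmonized <- m
      f <- file.path(out_dir, "harmonized.tsv")
      write_matrix_tsv(m, f)
      add_stage("harmonize", list(mode = mode, min_frac = min_frac), f)
    }, error = function(e) fail("harmonize", e))
  }

  if (stage_on("cluster")) {
    tryCatch({
      if (is.null(harmonized)) stop("cluster requires the harmonize stage")
      b <- block("cluster")
      k_range <- b$k_range %||% 2:8
      n_res <- b$n_resamples %||% 250
      sweep <- pac_sweep(harmonized, k_range, n_res,
                         item_frac = b$item_frac %||% 0.8, seed = seed)
      k <- sweep$best_k
      vote <- certainty_vote(harmonized, k = k)
      labels <- paste0("C", vote$modal)
      names(labels) <- names(vote$modal)
      f1 <- file.path(out_dir, "pac.tsv")
      f2 <- file.path(out_dir, "assignments.tsv")
      utils::write.table(data.frame(k = names(sweep$pac_by_k),
                                    pac = sweep$pac_by_k),
                         f1, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(sample = names(labels), cluster = labels,
                                    certainty = vote$certainty,
                                    n_runs = vote$n_runs),
                         f2, sep = "\t", quote = FALSE, row.names = FALSE)
      add_stage("cluster", list(k_range = k_range, n_resamples = n_res,
                                best_k = k), c(f1, f2))
    }, error = function(e) fail("cluster", e))
  }

  if (stage_on("markers")) {
    tryCatch({
      if (is.null(labels)) stop("markers requires the cluster stage")
      b <- block("markers")
      files <- character(0)
      for (g in sort(unique(labels))) {
        tab <- differential_table(harmonized, labels, g,
                                  p_thresh = b$p_thresh %||% 0.05,
                                  fc_thresh = b$fc_thresh %||% 1.5)
        top <- suppressWarnings(select_top_markers(tab, n = b$n_top %||% 5))
        f <- file.path(out_dir, paste0("markers_", g, ".tsv"))
        utils::write.table(attr(top, "table"), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
      }
      add_stage("markers", b, files)
    }, error = function(e) fail("markers", e))
  }

  if (stage_on("conserve")) {
    tryCatch({
      if (is.null(labels)) stop("conserve requires the cluster stage")
      b <- block("conserve")
      rows <- list()
      for (g in sort(unique(labels))) {
        rec <- subtype_correlation(harmonized, cohort$meth, labels, g,
                                   pairs = "own_gene_only",
                                   gene_annot = cohort$gene_annot,
                                   probe_annot = cohort$probe_annot,
                                   r_thresh = b$r_thresh %||% 0.7)
        cf <- conservation_fraction(rec, rownames(as_values(harmonized)))
        rows[[g]] <- data.frame(subtype = g, percent = cf$percent,
                                count = cf$count, n_universe = cf$n_universe)
      }
      f <- file.path(out_dir, "conservation.tsv")
      utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_stage("conserve", b, f)
    }, error = function(e) fail("conserve", e))
  }

  if (stage_on("cnv")) {
    tryCatch({
      if (is.null(labels)) stop("cnv requires the cluster stage")
      if (is.null(harmonized)) stop("cnv requires the harmonize stage")
      b <- block("cnv")
      sig <- gene_level_signal(harmonized, cohort$gene_annot,
                               unit = "per_group", labels = labels)
      segs <- call_segments(segment_signal(sig), cutoff = b$cutoff %||% 0.2)
      f <- file.path(out_dir, "proteome_cnv.seg")
      write_seg(segs, f)
      add_stage("cnv", b, f)
    }, error = function(e) fail("cnv", e))
  }

  if (stage_on("glycan")) {
    tryCatch({
      b <- block("glycan")
      sim <- simulate_glycan_panel(b$n_groups %||% 4,
                                   b$compositions_per_group %||% 40,
                                   ppm_noise = b$ppm_noise %||% 3, seed = seed)
      matches <- lapply(sim$observed_mass, decompose_mass,
                        tol_ppm = b$tol_ppm %||% 10)
      best <- lapply(matches, function(x) x$best %||% NA)
      stats_out <- group_stats(sim$panel, best)
      f <- file.path(out_dir, "glycan_groups.tsv")
      utils::write.table(stats_out$per_group, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_stage("glycan", b, f)
    }, error = function(e) fail("glycan", e))
  }

  if (stage_on("dhscore")) {
    tryCatch({
      b <- block("dhscore")
      sim <- simulate_stain_image(b$width %||% 120, b$height %||% 120,
                                  blobs = b$blobs %||% list(
                                    list(n_pixels = 500, bin = "strong"),
                                    list(n_pixels = 300, bin = "medium"),
                                    list(n_pixels = 200, bin = "weak")),
                                  seed = seed)
      res <- dh_score(sim$image)
      f <- file.path(out_dir, "dh_scores.csv")
      utils::write.csv(data.frame(image = "synthetic", dh = res$dh,
                                  n_strong = res$n_strong,
                                  n_medium = res$n_medium,
                                  n_weak = res$n_weak,
                                  tissue_area = res$tissue_area),
                       f, row.names = FALSE)
      add_stage("dhscore", list(), f)
    }, error = function(e) fail("dhscore", e))
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
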