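#!/usr/bin/env Rscript
# Generate the reference synthetic multiomic cohort: 120 samples, 6 planted
# proteome subtypes (60 markers each, +1.5 log2), 1500 proteins, 2000 CpGs,
# 4 TMT-like batches (location sd 1), 25% MCAR missingness, 40% own-gene
# CpG coupling (rho 0.9) in subtype 1, a 7p gain (+0.3, 60% of subtype 2,
# attenuation 0.5 into the proteome) and 9 blood-contaminated samples.
# Writes matrices, annotation and ground truth under results/cohort/.

library(medullomix)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(
  n_samples = 120, n_proteins = 1500, n_cpgs = 2000, k_subtypes = 6,
  n_markers_per_subtype = 60, marker_shift = 1.5, noise_sd = 1,
  n_batches = 4, batch_location_sd = 1, missing_frac = 0.25,
  missing_mode = "MCAR",
  coupling_frac = c(0.4, 0, 0, 0, 0, 0), coupling_rho = 0.9,
  cnv_events = list(cnv_event("7p", "gain", 0.3, subtype = 2,
                              carrier_frac = 0.6, attenuation = 0.5)),
  n_contaminated = 9, seed = 20260101)

co <- simulate_cohort(cfg)

write_matrix_tsv(co$prot, file.path(out, "abundance.tsv"))
write_matrix_tsv(co$meth, file.path(out, "methylation.tsv"))
write_matrix_tsv(co$meth_cnv, file.path(out, "methylome_cnv_signal.tsv"))
write.table(co$probe_annot, file.path(out, "probe_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_bed(co$gene_annot, file.path(out, "genes.bed"))
jsonlite::write_json(
  list(subtype = as.list(co$truth$subtype),
       batch = as.list(co$truth$batch),
       markers = co$truth$markers,
       contaminated = co$truth$contaminated,
       blood_panel = co$truth$blood_panel,
       coupled = co$truth$coupled),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("cohort: %d proteins x %d samples, %.1f%% missing",
                nrow(co$prot$values), ncol(co$prot$values),
                100 * mean(is.na(co$prot$values))))
message(sprintf("coupled pairs: %d; CNV carriers: %d; contaminated: %d",
                nrow(co$truth$coupled),
                length(co$truth$cnv_events[[1]]$carriers),
                length(co$truth$contaminated)))
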