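#!/usr/bin/env Rscript
# Harmonize the simulated proteome the way TMT cohorts are integrated:
# per-sample median normalization, batch location equalization over
# missingness-dissection blocks, row mean centering (SILAC-ratio-like),
# 30% global validity filter, and blood-contamination flagging.
# Reads results/cohort/, writes results/harmonized/.

library(medullomix)

out <- "results/harmonized"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
values <- read_matrix_tsv("results/cohort/abundance.tsv")
prot <- abundance_matrix(values, batch = truth$batch[colnames(values)])

flags <- flag_contaminated_samples(prot, truth$blood_panel, z_thresh = 3)
message(sprintf("flagged %d blood-contaminated sample(s): %s",
                sum(flags), paste(names(flags)[flags], collapse = ", ")))
hit <- intersect(names(flags)[flags], truth$contaminated)
message(sprintf("  %d/%d planted contaminations recovered",
                length(hit), length(truth$contaminated)))

keep <- !flags
m <- abundance_matrix(prot$values[, keep], batch = prot$batch[keep])
m <- median_normalize_columns(m)
m <- dissect_and_adjust_batches(m, "location")
m <- row_mean_center(m)
m <- filter_validity(m, 0.3, "global")

write_matrix_tsv(m, file.path(out, "abundance_harmonized.tsv"))
write.table(data.frame(sample = names(flags), contaminated = unname(flags)),
            file.path(out, "contamination_flags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("harmonized matrix: %d proteins x %d samples",
                nrow(m$values), ncol(m$values)))
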