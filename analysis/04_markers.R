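#!/usr/bin/env Rscript
# Subtype biomarkers: one-vs-rest Student t tests (p < 0.05, |log2FC| > 1.5,
# features in >= 30% of samples of every subtype), ANOVA across subtypes,
# and the top-5 combined-rank biomarker panels. Writes results/markers/.

library(medullomix)

out <- "results/markers"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- read_matrix_tsv("results/harmonized/abundance_harmonized.tsv")
assign_tab <- read.delim("results/consensus/assignments.tsv")
labels <- setNames(assign_tab$cluster, assign_tab$sample)[colnames(m)]
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
planted <- unlist(truth$subtype)

aov_tab <- anova_across(m, labels)
message(sprintf("ANOVA: %d/%d features pass p < 0.05",
                sum(aov_tab$pass, na.rm = TRUE), nrow(aov_tab)))
write.table(aov_tab, file.path(out, "anova.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

panel <- list()
for (g in sort(unique(labels))) {
  tab <- differential_table(m, labels, g)
  top <- suppressWarnings(select_top_markers(tab, n = 5))
  write.table(tab, file.path(out, paste0("differential_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # which planted subtype does this cluster correspond to?
  s_match <- names(which.max(table(planted[names(labels)[labels == g]])))
  mk <- truth$markers[[paste0("subtype", s_match)]]
  message(sprintf("%s: %d significant, top5 = %s (%d/5 planted markers of subtype %s)",
                  g, sum(tab$significant), paste(top, collapse = ","),
                  length(intersect(top, mk)), s_match))
  panel[[g]] <- top
}
write.table(data.frame(cluster = rep(names(panel), lengths(panel)),
                       marker = unlist(panel)),
            file.path(out, "top5_markers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
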