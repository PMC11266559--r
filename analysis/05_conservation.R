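#!/usr/bin/env Rscript
# Proteome <-> DNA-methylome feature conservation: probe filtering,
# subtype-restricted own-gene Pearson correlation at r > 0.7, conservation
# fractions per subtype, CpG positional distribution, DMR aggregation and a
# tri-omic per-gene correlation demonstration. Writes results/conservation/.

library(medullomix)

out <- "results/conservation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prot <- read_matrix_tsv("results/harmonized/abundance_harmonized.tsv")
meth <- read_matrix_tsv("results/cohort/methylation.tsv")
probe_annot <- read.delim("results/cohort/probe_annotation.tsv")
gene_annot <- read_gene_bed("results/cohort/genes.bed")
assign_tab <- read.delim("results/consensus/assignments.tsv")
labels <- setNames(assign_tab$cluster, assign_tab$sample)[colnames(prot)]

meth <- filter_probes(meth, probe_annot)
message(sprintf("probe filter removed %s",
                paste(names(attr(meth, "n_removed")),
                      attr(meth, "n_removed"), collapse = ", ")))

universe <- rownames(prot)
rows <- list()
for (g in sort(unique(labels))) {
  rec <- subtype_correlation(prot, meth, labels, g,
                             gene_annot = gene_annot,
                             probe_annot = probe_annot, r_thresh = 0.7)
  cf <- conservation_fraction(rec, universe)
  rows[[g]] <- data.frame(subtype = g, percent = cf$percent,
                          count = cf$count, n_universe = cf$n_universe)
  message(sprintf("%s: %.2f%% of proteins (n = %d) correlate with >= 1 own-gene CpG",
                  g, cf$percent, cf$count))
  if (cf$count > 5) {
    pd <- position_distribution(rec, probe_annot)
    message(sprintf("  TSS-region share of passing CpGs: %.1f%%",
                    100 * attr(pd, "tss_aggregate")))
    write.table(data.frame(feature_class = names(pd), proportion = pd),
                file.path(out, paste0("positions_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rec$r <- round(rec$r, 4)
  write.table(rec[rec$passes, ],
              file.path(out, paste0("passing_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(do.call(rbind, rows), file.path(out, "conservation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# DMR aggregation demo: a run of 10 retained chrom-1 probes re-spaced to
# satisfy the < 1000 nt gap rule (the uniform synthetic manifest has no
# natural dense runs)
pa <- probe_annot[probe_annot$probe_id %in% rownames(meth), ]
dmr_probes <- head(pa$probe_id[pa$chrom == "1"], 10)
pa2 <- probe_annot
pa2$pos[match(dmr_probes, pa2$probe_id)] <- seq(1000, by = 500, length.out = 10)
dmr <- list(list(dmr_id = "DMR_demo", chrom = "1", probes = dmr_probes))
agg <- aggregate_dmr(meth, dmr, pa2)
write_matrix_tsv(agg, file.path(out, "dmr_matrix.tsv"))
message(sprintf("aggregated %d DMR row(s) over %d samples", nrow(agg), ncol(agg)))
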