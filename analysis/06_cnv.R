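#!/usr/bin/env Rscript
# Expression-derived copy number: map harmonized protein abundance to gene
# positions, segment per sample by recursive binary splitting, call
# gain/loss at the inclusive |0.2| cutoff, build per-subtype arm frequency
# profiles on both platforms and correlate them arm-wise.
# Writes results/cnv/.

library(medullomix)

out <- "results/cnv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prot <- read_matrix_tsv("results/harmonized/abundance_harmonized.tsv")
meth_cnv <- read_matrix_tsv("results/cohort/methylome_cnv_signal.tsv")
gene_annot <- read_gene_bed("results/cohort/genes.bed")
assign_tab <- read.delim("results/consensus/assignments.tsv")
labels <- setNames(assign_tab$cluster, assign_tab$sample)[colnames(prot)]

sig <- gene_level_signal(prot, gene_annot, "per_sample")
message(sprintf("%d genes mapped (%d proteins unmapped)",
                nrow(sig$values), sig$n_unmapped))
segs <- call_segments(segment_signal(sig), cutoff = 0.2)
write_seg(segs, file.path(out, "proteome.seg"))

msig <- list(genes = sig$genes,
             values = meth_cnv[rownames(sig$values), colnames(sig$values)])
msegs <- call_segments(segment_signal(msig), cutoff = 0.2)
write_seg(msegs, file.path(out, "methylome.seg"))

fp <- frequency_profile(segs, gene_annot, labels)
mfp <- frequency_profile(msegs, gene_annot, labels)
write.table(fp, file.path(out, "proteome_arm_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mfp, file.path(out, "methylome_arm_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (g in sort(unique(labels))) {
  m1 <- mfp[mfp$group == g, ]
  top <- m1[which.max(m1$gain_pct), ]
  if (top$gain_pct > 0)
    message(sprintf("%s: top methylome gain bin %s at %.1f%%",
                    g, top$bin, top$gain_pct))
}

xc <- cross_platform_correlation(segs, msegs, gene_annot, labels)
write.table(xc, file.path(out, "cross_platform_r.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("arm-level proteome/methylome correlation per subtype:")
print(xc)
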