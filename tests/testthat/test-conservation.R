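test_that("beta/M conversions match the log2 ratio identity", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  # boundary values are clamped, not infinite
  expect_true(is.finite(beta_to_m(0)))
  expect_true(is.finite(beta_to_m(1)))
})

test_that("probe filtering drops flagged and sex-chromosome probes", {
  annot <- data.frame(
    probe_id = paste0("cg", 1:100),
    chrom = c(rep("1", 90), rep("X", 6), rep("Y", 4)),
    pos = 1:100, gene = NA, feature_class = "Body",
    quality_flag = c(rep(TRUE, 30), rep(FALSE, 70)),
    snp_flag = c(rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 50)),
    stringsAsFactors = FALSE)
  meth <- matrix(0, 100, 3, dimnames = list(annot$probe_id, paste0("S", 1:3)))
  out <- filter_probes(meth, annot)
  expect_equal(nrow(out), 100 - 30 - 20 - 10)
  expect_equal(sum(attr(out, "n_removed")), 60)
  expect_equal(unname(attr(out, "n_removed")["quality"]), 30)
  # chrX probe removed when the sex filter is on, kept when off
  expect_false(any(annot$chrom[match(rownames(out), annot$probe_id)] %in%
                   c("X", "Y")))
  out2 <- filter_probes(meth, annot, drop_flags = c("quality", "snp"))
  expect_true("cg95" %in% rownames(out2))
  # no flags set: identity
  annot0 <- annot; annot0$quality_flag <- FALSE; annot0$snp_flag <- FALSE
  annot0$chrom <- "1"
  expect_equal(nrow(filter_probes(meth, annot0)), 100)
})

test_that("a 20x20 correlation block equals a brute-force double loop", {
  set.seed(11)
  prot <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(paste0("P", 1:20), paste0("S", 1:15)))
  meth <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(paste0("cg", 1:20), paste0("S", 1:15)))
  prot[sample(length(prot), 40)] <- NA
  labels <- rep("A", 15)
  rec <- subtype_correlation(prot, meth, labels, "A", pairs = "all",
                             min_overlap = 5)
  # independent double loop
  for (i in seq_len(nrow(rec))) {
    x <- prot[rec$protein[i], ]; y <- meth[rec$cpg[i], ]
    ok <- !is.na(x) & !is.na(y)
    want <- if (sum(ok) >= 5) cor(x[ok], y[ok]) else NA_real_
    expect_identical(rec$r[i], want)
  }
  expect_equal(nrow(rec), 400)
})

test_that("planted coupling passes the 0.7 cutoff, null pairs do not", {
  set.seed(13)
  n <- 30
  z <- rnorm(n)
  prot <- rbind(P1 = z, P2 = rnorm(n))
  meth <- rbind(cg1 = 0.9 * z + sqrt(1 - 0.81) * rnorm(n), cg2 = rnorm(n))
  colnames(prot) <- colnames(meth) <- paste0("S", 1:n)
  labels <- rep("A", n)
  rec <- subtype_correlation(prot, meth, labels, "A", pairs = "all")
  expect_true(rec$passes[rec$protein == "P1" & rec$cpg == "cg1"])
  expect_false(rec$passes[rec$protein == "P2" & rec$cpg == "cg2"])
  # constant protein: r undefined, emitted with passes = FALSE
  prot2 <- rbind(P1 = rep(1, n)); colnames(prot2) <- colnames(meth)
  rec2 <- subtype_correlation(prot2, meth, labels, "A", pairs = "all")
  expect_true(all(is.na(rec2$r)))
  expect_false(any(rec2$passes))
  # signed rule: strong negative correlation fails unless use_abs
  meth3 <- rbind(cg1 = -z + 0.01 * rnorm(n)); colnames(meth3) <- colnames(prot)
  r3 <- subtype_correlation(prot, meth3, labels, "A", pairs = "all")
  expect_false(r3$passes[r3$protein == "P1"])
  r3a <- subtype_correlation(prot, meth3, labels, "A", pairs = "all",
                             use_abs = TRUE)
  expect_true(r3a$passes[r3a$protein == "P1"])
})

test_that("conservation fraction counts proteins with passing own-gene CpGs", {
  rec <- data.frame(protein = c("P1", "P1", "P2", "P3", "P4"),
                    cpg = paste0("cg", 1:5),
                    own_gene = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                    passes = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cf <- conservation_fraction(rec, paste0("P", 1:10))
  # P1 (two records, counted once) and P2; P3 passes but not own-gene
  expect_equal(cf$count, 2)
  expect_equal(cf$percent, 20)
  expect_equal(conservation_fraction(rec[0, ], paste0("P", 1:10))$percent, 0)
  # 40 of 100 proteins -> 40%
  rec2 <- data.frame(protein = paste0("P", 1:40), cpg = paste0("cg", 1:40),
                     own_gene = TRUE, passes = TRUE)
  expect_equal(conservation_fraction(rec2, paste0("P", 1:100))$percent, 40)
})

test_that("positional distribution aggregates TSS classes", {
  annot <- data.frame(probe_id = paste0("cg", 1:4),
                      feature_class = c("TSS200", "TSS200", "Body", "Body"))
  rec <- data.frame(protein = "P1", cpg = annot$probe_id,
                    own_gene = TRUE, passes = TRUE)
  pd <- position_distribution(rec, annot)
  expect_equal(sum(pd), 1, tolerance = 1e-9)
  expect_equal(attr(pd, "tss_aggregate"), 0.5)
  rec_body <- rec[3:4, ]
  pdb <- position_distribution(rec_body, annot)
  expect_equal(unname(pdb["Body"]), 1)
  expect_error(position_distribution(rec[0, ], annot), "no passing")
})

test_that("DMR validation enforces the probe-run rules", {
  annot <- data.frame(probe_id = paste0("cg", 1:30), chrom = "1",
                      pos = seq(100, by = 500, length.out = 30))
  good <- list(list(dmr_id = "d1", chrom = "1", probes = paste0("cg", 1:10)))
  expect_silent(validate_dmr_table(good, annot))
  expect_error(validate_dmr_table(
    list(list(dmr_id = "d2", chrom = "1", probes = paste0("cg", 1:9))),
    annot), "fewer than 10")
  # a gap of >= 1000 nt between consecutive members
  annot2 <- annot; annot2$pos[5] <- annot2$pos[4] + 2000
  annot2$pos[6:30] <- annot2$pos[5] + seq(500, by = 500, length.out = 25)
  expect_error(validate_dmr_table(good, annot2), "gap")
})

test_that("DMR aggregation takes per-sample means over member probes", {
  annot <- data.frame(probe_id = paste0("cg", 1:10), chrom = "1",
                      pos = seq(100, by = 500, length.out = 10))
  meth <- matrix(rep(1:10 / 10, 3), 10, 3,
                 dimnames = list(annot$probe_id, paste0("S", 1:3)))
  dmrs <- list(list(dmr_id = "d1", chrom = "1", probes = annot$probe_id))
  # identical probes: the DMR row equals any member row
  meth_id <- matrix(2, 10, 3, dimnames = dimnames(meth))
  expect_equal(unname(aggregate_dmr(meth_id, dmrs, annot)["d1", ]),
               rep(2, 3))
  # a missing member: mean over the remaining nine
  meth2 <- meth; meth2["cg1", "S1"] <- NA
  agg <- aggregate_dmr(meth2, dmrs, annot)
  expect_equal(unname(agg["d1", "S1"]), mean(meth[2:10, "S1"]))
  expect_equal(unname(agg["d1", "S2"]), mean(meth[, "S2"]))
})

test_that("tri-omic correlation flags genes passing on all three levels", {
  set.seed(17)
  n <- 60
  s <- paste0("S", 1:n)
  z <- rnorm(n)
  prot <- rbind(CCT2 = z + 0.05 * rnorm(n), NULLG = rnorm(n))
  rna <- rbind(CCT2 = z + 0.05 * rnorm(n), NULLG = rnorm(n))
  meth <- rbind(CCT2 = -z + 0.05 * rnorm(n), NULLG = rnorm(n))
  colnames(prot) <- colnames(rna) <- colnames(meth) <- s
  out <- triomics_correlation(prot, rna, meth, c("CCT2", "NULLG"))
  expect_true(out$passes_all[out$gene == "CCT2"])
  expect_false(out$passes_all[out$gene == "NULLG"])
  # independent noise at n = 60 passes nowhere
  expect_false(any(out[out$gene == "NULLG",
                       c("pass_prot_rna", "pass_rna_cpg", "pass_prot_cpg")]))
  # single-sample overlap: everything undefined
  out1 <- triomics_correlation(prot[, 1:4], rna[, 1:4], meth[, 1:4],
                               "CCT2", min_overlap = 5)
  expect_true(is.na(out1$r_prot_rna))
  expect_false(out1$passes_all)
})

test_that("simulated coupling is recovered as conservation percentages", {
  co <- cached_cohort(cohort_config(n_samples = 120, n_proteins = 400,
                                    n_cpgs = 700, k_subtypes = 4,
                                    n_markers_per_subtype = 20,
                                    coupling_frac = c(0.4, 0, 0, 0),
                                    coupling_rho = 0.9, seed = 71))
  labels <- paste0("C", co$truth$subtype)
  m <- harmonize_chain(co$prot)
  universe <- rownames(m$values)
  rec_c <- subtype_correlation(m, co$meth, labels, "C1",
                               gene_annot = co$gene_annot,
                               probe_annot = co$probe_annot)
  cf_c <- conservation_fraction(rec_c, universe)
  expect_lt(abs(cf_c$percent - 40), 7)
  rec_u <- subtype_correlation(m, co$meth, labels, "C2",
                               gene_annot = co$gene_annot,
                               probe_annot = co$probe_annot)
  expect_lt(conservation_fraction(rec_u, universe)$percent, 2)
})
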