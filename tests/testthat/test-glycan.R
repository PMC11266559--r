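# Independent elemental-composition oracle. Works from free-monosaccharide
# formulas and per-monosaccharide methylation-site counts, removing one
# water and two methyl sites per glycosidic bond — a different
# parameterization from the package's in-chain residue masses.
oracle_mass <- function(counts, reduced = TRUE) {
  am <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  free_formula <- list(  # full monosaccharides, C/H/N/O
    Hex = c(6, 12, 0, 6), HexNAc = c(8, 15, 1, 6), dHex = c(6, 12, 0, 5),
    NeuAc = c(11, 19, 1, 9), NeuGc = c(11, 19, 1, 10))
  free_sites <- c(Hex = 5, HexNAc = 5, dHex = 4, NeuAc = 7, NeuGc = 8)
  counts <- counts[counts > 0]
  n <- sum(counts)
  f <- c(0, 0, 0, 0)
  for (r in names(counts)) f <- f + counts[[r]] * free_formula[[r]]
  f <- f - c(0, 2, 0, 1) * (n - 1)            # one H2O per bond
  sites <- sum(free_sites[names(counts)] * counts) - 2 * (n - 1)
  if (reduced) { f <- f + c(0, 2, 0, 0); sites <- sites + 1 }
  f <- f + sites * c(1, 2, 0, 0)              # CH2 per methylation
  sum(f * am[c("C", "H", "N", "O")])
}

test_that("permethylated-reduced masses match the elemental oracle", {
  cases <- list(
    c(Hex = 3, HexNAc = 2),
    c(Hex = 5, HexNAc = 2),
    c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 2),
    c(Hex = 9, HexNAc = 2),
    c(Hex = 4, HexNAc = 3, dHex = 2, NeuAc = 1, NeuGc = 1))
  for (cs in cases) {
    cmp <- do.call(glycan_composition, as.list(cs))
    expect_equal(composition_mass(cmp), oracle_mass(cs), tolerance = 1e-6)
    expect_equal(composition_mass(cmp, "free"),
                 oracle_mass(cs, reduced = FALSE), tolerance = 1e-6)
  }
  # frozen value for the permethylated-reduced pentasaccharide core,
  # C52 H96 N2 O26 summed from atomic masses
  expect_equal(composition_mass(glycan_composition(Hex = 3, HexNAc = 2)),
               1164.625131, tolerance = 1e-6)
  expect_error(composition_mass(c(Foo = 1)), "unknown residue")
})

test_that("composition mass is additive in residues", {
  m52 <- composition_mass(glycan_composition(Hex = 5, HexNAc = 2))
  m42 <- composition_mass(glycan_composition(Hex = 4, HexNAc = 2))
  hex_residue <- medullomix:::permethylated_residue_masses()["Hex"]
  expect_equal(m52 - m42, unname(hex_residue), tolerance = 1e-9)
  # empty composition carries only the end-group adjustment
  end <- composition_mass(glycan_composition())
  expect_gt(end, 0)
  expect_equal(composition_mass(glycan_composition(Hex = 1), "free") -
               composition_mass(glycan_composition(), "free"),
               unname(hex_residue), tolerance = 1e-9)
})

test_that("mass decomposition round-trips exact masses", {
  cmp <- glycan_composition(Hex = 5, HexNAc = 2)
  match <- decompose_mass(composition_mass(cmp), tol_ppm = 5)
  expect_equal(format(match$best), format(cmp))
  expect_equal(match$ppm_errors[1], 0, tolerance = 1e-9)
  # far below any valid core mass: empty candidate set
  expect_length(decompose_mass(100)$candidates, 0)
})

test_that("decomposition equals a brute-force enumeration", {
  bounds <- c(Hex = 15, HexNAc = 10, dHex = 6, NeuAc = 6, NeuGc = 0)
  grid <- expand.grid(Hex = 0:15, HexNAc = 0:10, dHex = 0:6, NeuAc = 0:6)
  keep <- grid$HexNAc >= 2 & grid$Hex >= 2 &
    grid$NeuAc <= grid$HexNAc - 1 & grid$dHex <= grid$HexNAc + 1
  grid <- grid[keep, ]
  rm <- medullomix:::permethylated_residue_masses()
  end <- composition_mass(glycan_composition())
  grid_mass <- end + as.matrix(grid) %*% rm[c("Hex", "HexNAc", "dHex", "NeuAc")]
  set.seed(31)
  masses <- runif(200, 1000, 4000)
  for (obs in masses) {
    hits <- which(abs(1e6 * (obs - grid_mass) / grid_mass) <= 10)
    got <- decompose_mass(obs, tol_ppm = 10, bounds = bounds)
    got_keys <- sort(vapply(got$candidates, format, ""))
    want_keys <- sort(apply(grid[hits, , drop = FALSE], 1, function(r) {
      nz <- r[r > 0]
      paste0(names(nz), nz, collapse = "")
    }))
    expect_identical(got_keys, unname(want_keys))
  }
})

test_that("composition classes follow the rule table", {
  expect_equal(classify_composition(glycan_composition(Hex = 9, HexNAc = 2)),
               "high_mannose")
  expect_equal(classify_composition(glycan_composition(Hex = 3, HexNAc = 2)),
               "paucimannose")
  expect_equal(classify_composition(glycan_composition(Hex = 6, HexNAc = 3)),
               "hybrid")
  cplx <- glycan_composition(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 2)
  expect_equal(classify_composition(cplx), "complex")
  expect_true(is_fucosylated(cplx))
  expect_true(is_sialylated(cplx))
  expect_equal(classify_composition(glycan_composition(Hex = 4, HexNAc = 3)),
               "complex")
  # fucosylated high-mannose composition is 'other'
  expect_equal(classify_composition(glycan_composition(Hex = 6, HexNAc = 2,
                                                       dHex = 1)), "other")
})

test_that("plausibility rules gate decomposition candidates", {
  # NeuAc-heavy composition valid only with rules disabled
  cmp <- glycan_composition(Hex = 2, HexNAc = 2, NeuAc = 3)
  m <- composition_mass(cmp)
  with_rules <- decompose_mass(m, tol_ppm = 5,
                               bounds = c(Hex = 6, HexNAc = 6, dHex = 3,
                                          NeuAc = 6, NeuGc = 0))
  keys <- vapply(with_rules$candidates, format, "")
  expect_false(format(cmp) %in% keys)
  no_rules <- decompose_mass(m, tol_ppm = 5,
                             bounds = c(Hex = 6, HexNAc = 6, dHex = 3,
                                        NeuAc = 6, NeuGc = 0), rules = "none")
  expect_true(format(cmp) %in% vapply(no_rules$candidates, format, ""))
})

test_that("zero-noise panels decompose back to their generating composition", {
  sim <- simulate_glycan_panel(3, 25, ppm_noise = 0, seed = 41)
  for (id in names(sim$observed_mass)) {
    match <- decompose_mass(sim$observed_mass[[id]], tol_ppm = 1)
    expect_true(format(sim$truth[[id]]) %in%
                vapply(match$candidates, format, ""))
  }
})

test_that("noisy masses keep the truth among candidates at 10 ppm", {
  sim <- simulate_glycan_panel(2, 25, ppm_noise = 3, seed = 43)
  found <- vapply(names(sim$observed_mass), function(id) {
    match <- decompose_mass(sim$observed_mass[[id]], tol_ppm = 10)
    format(sim$truth[[id]]) %in% vapply(match$candidates, format, "")
  }, TRUE)
  expect_true(all(found))
})

test_that("group statistics report planted fucosylation exactly", {
  sim <- simulate_glycan_panel(3, 30, ppm_noise = 0, seed = 47,
                               fuc_frac = c(1, 0.7, 0.2), sia_frac = 0.5)
  gs <- group_stats(sim$panel, sim$truth)
  pg <- gs$per_group
  expect_equal(pg$fuc_pct_count[pg$group == "G1"], 100)
  expect_equal(pg$fuc_pct_count[pg$group == "G2"], 70)
  expect_equal(pg$fuc_pct_count[pg$group == "G3"], 20)
  expect_true(all(pg$sia_pct_abundance >= 0 & pg$sia_pct_abundance <= 100))
  # identical sets give full Venn overlap
  panel2 <- sim$panel[, c(1, 1)]
  colnames(panel2) <- c("A", "B")
  gs2 <- group_stats(panel2, sim$truth)
  expect_equal(gs2$venn$shared, length(gs2$sets$A))
  expect_equal(gs2$venn$only_a + gs2$venn$only_b, 0)
})

test_that("differential glycan analysis delegates to the marker machinery", {
  set.seed(53)
  groups <- rep(c("A", "B"), each = 6)
  panel <- matrix(rnorm(40 * 12, mean = 25), 40, 12,
                  dimnames = list(paste0("gly", 1:40), paste0("S", 1:12)))
  panel[1, groups == "A"] <- panel[1, groups == "A"] + 4
  out <- differential_glycans(panel, groups)
  expect_true(out$tables$A$significant[out$tables$A$feature == "gly1"])
  expect_lt(out$anova$p[1], 0.01)
  expect_equal(nrow(out$anova), 40)
})
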