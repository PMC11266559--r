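# Monoisotopic atomic masses (IUPAC).
.atomic <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)

formula_mass <- function(counts) sum(.atomic[names(counts)] * counts)

# In-chain (water-loss) residue elemental formulas and the number of
# methylatable sites each residue carries inside a chain (free hydroxyls +
# amide NH + carboxyl); permethylation adds one CH2 per site.
.residues <- list(
  Hex    = list(formula = c(C = 6,  H = 10, N = 0, O = 5), sites = 3),
  HexNAc = list(formula = c(C = 8,  H = 13, N = 1, O = 5), sites = 3),
  dHex   = list(formula = c(C = 6,  H = 10, N = 0, O = 4), sites = 2),
  NeuAc  = list(formula = c(C = 11, H = 17, N = 1, O = 8), sites = 5),
  NeuGc  = list(formula = c(C = 11, H = 17, N = 1, O = 9), sites = 6)
)
.residue_order <- names(.residues)
.ch2 <- formula_mass(c(C = 1, H = 2))
.h2o <- formula_mass(c(H = 2, O = 1))
.h2 <- formula_mass(c(H = 2))

# Permethylated in-chain residue masses (native + sites x CH2).
permethylated_residue_masses <- function() {
  vapply(.residues, function(r) formula_mass(r$formula) + r$sites * .ch2, 0)
}

#' N-glycan monosaccharide composition
#'
#' Counts of the five mass-distinguishable residue classes. Hexose isomers
#' (Man/Gal/Glc) and HexNAc isomers (GlcNAc/GalNAc) are indistinguishable by
#' mass.
#'
#' @param Hex,HexNAc,dHex,NeuAc,NeuGc non-negative integer counts.
#' @return Named integer vector of class `glycan_composition`.
#' @export
glycan_composition <- function(Hex = 0, HexNAc = 0, dHex = 0, NeuAc = 0,
                               NeuGc = 0) {
  x <- c(Hex = unname(Hex), HexNAc = unname(HexNAc), dHex = unname(dHex),
         NeuAc = unname(NeuAc), NeuGc = unname(NeuGc))
  if (any(x < 0) || any(x != floor(x))) stop("counts must be non-negative integers")
  structure(as.integer(x), names = names(x), class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (length(nz) == 0) return("(empty)")
  paste0(names(nz), unclass(nz), collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), sprintf(" [%.4f Da, %s]\n", composition_mass(x),
                         classify_composition(x)), sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a (derivatized) glycan composition
#'
#' Sums permethylated in-chain residue masses plus the end-group adjustment.
#' For a reduced, permethylated glycan the ends contribute
#' H2O + H2 + 3 x CH2 (chain-terminal water, reducing-end reduction to the
#' alditol, and the three extra methylation sites the free chain ends and
#' the opened ring expose); for a free reducing end, H2O + 2 x CH2.
#'
#' @param c a [glycan_composition()] or named count vector.
#' @param end_group `"reduced_permethylated"` (default) or `"free"`
#'   (permethylated, free reducing end).
#' @return Mass in Da.
#' @export
composition_mass <- function(c, end_group = c("reduced_permethylated", "free")) {
  end_group <- match.arg(end_group)
  counts <- as_counts(c)
  rm <- permethylated_residue_masses()
  end <- if (end_group == "reduced_permethylated") .h2o + .h2 + 3 * .ch2
         else .h2o + 2 * .ch2
  sum(rm[names(counts)] * counts) + end
}

as_counts <- function(c) {
  if (inherits(c, "glycan_composition")) return(stats::setNames(unclass(c), names(c)))
  if (is.null(names(c))) stop("composition must be named")
  unknown <- setdiff(names(c), .residue_order)
  if (length(unknown)) stop("unknown residue key(s): ", paste(unknown, collapse = ", "))
  full <- stats::setNames(integer(length(.residue_order)), .residue_order)
  full[names(c)] <- as.integer(c)
  full
}

# Biosynthetic plausibility rules for N-glycan compositions.
passes_rules <- function(counts, rules = c("n_glycan_core", "none")) {
  rules <- match.arg(rules)
  if (rules == "none") return(TRUE)
  sia <- counts["NeuAc"] + counts["NeuGc"]
  counts["HexNAc"] >= 2 && counts["Hex"] >= 2 &&
    sia <= counts["HexNAc"] - 1 && counts["dHex"] <= counts["HexNAc"] + 1
}

#' Decompose an observed neutral mass into candidate compositions
#'
#' Exhaustive bounded depth-first search with mass pruning over the residue
#' alphabet; keeps compositions whose theoretical mass lies within `tol_ppm`
#' of the observation and which pass the plausibility rules (default:
#' HexNAc >= 2, Hex >= 2, NeuAc + NeuGc <= HexNAc - 1, dHex <= HexNAc + 1).
#'
#' @param observed neutral monoisotopic mass, Da.
#' @param tol_ppm matching tolerance in parts per million.
#' @param bounds named integer vector of per-residue maximal counts.
#' @param rules `"n_glycan_core"` or `"none"`.
#' @param end_group see [composition_mass()].
#' @return A list of class `glycan_match`: `observed_mass`, `candidates`
#'   (list of compositions, sorted by `|ppm_error|`), `ppm_errors`, `best`
#'   (composition or NULL).
#' @export
decompose_mass <- function(observed, tol_ppm = 10,
                           bounds = c(Hex = 15, HexNAc = 10, dHex = 6,
                                      NeuAc = 6, NeuGc = 0),
                           rules = "n_glycan_core",
                           end_group = "reduced_permethylated") {
  if (observed <= 0) stop("observed mass must be positive")
  bounds <- as_counts(bounds)
  rm <- permethylated_residue_masses()
  end <- composition_mass(glycan_composition(), end_group)
  tol <- observed * tol_ppm * 1e-6 * 1.01  # search window; exact ppm check below
  target <- observed - end
  found <- list(); errs <- numeric(0)
  counts <- stats::setNames(integer(5), .residue_order)
  recurse <- function(level, remaining) {
    if (level > 5) {
      theo <- observed - remaining
      if (theo > 0 && abs(1e6 * remaining / theo) <= tol_ppm &&
          passes_rules(counts, rules)) {
        found[[length(found) + 1]] <<- glycan_composition(
          counts["Hex"], counts["HexNAc"], counts["dHex"],
          counts["NeuAc"], counts["NeuGc"])
        errs[length(errs) + 1] <<- 1e6 * (observed - theo) / theo
      }
      return(invisible())
    }
    res <- .residue_order[level]
    max_n <- min(bounds[res], floor((remaining + tol) / rm[res]))
    if (is.na(max_n) || max_n < 0) max_n <- -1L
    for (nres in 0:max_n) {
      counts[res] <<- nres
      rem <- remaining - nres * rm[res]
      # prune: even the empty tail cannot reach the window
      if (rem < -tol) { counts[res] <<- 0L; break }
      recurse(level + 1, rem)
    }
    counts[res] <<- 0L
    invisible()
  }
  recurse(1, target)
  o <- order(abs(errs))
  structure(list(observed_mass = observed,
                 candidates = found[o], ppm_errors = errs[o],
                 best = if (length(found)) found[[o[1]]] else NULL),
            class = "glycan_match")
}

#' Classify a composition into an N-glycan type
#'
#' Mass-composition approximation of the structural classes: antenna
#' topology and bisecting GlcNAc are not inferable from composition, so
#' "bisecting" is never emitted.
#'
#' * high-mannose: HexNAc = 2, Hex >= 5, no dHex, no sialic acid
#' * paucimannose: HexNAc = 2, Hex <= 4
#' * hybrid: HexNAc = 3, Hex >= 5
#' * complex: HexNAc >= 4, or HexNAc = 3 with Hex <= 4
#' * other: anything else (e.g. fucosylated or sialylated Hex >= 5 with
#'   HexNAc = 2)
#'
#' @param c a [glycan_composition()].
#' @return One of `"high_mannose"`, `"paucimannose"`, `"hybrid"`,
#'   `"complex"`, `"other"`.
#' @export
classify_composition <- function(c) {
  x <- as_counts(c)
  sia <- x["NeuAc"] + x["NeuGc"]
  if (x["HexNAc"] == 2 && x["Hex"] >= 5 && x["dHex"] == 0 && sia == 0)
    return("high_mannose")
  if (x["HexNAc"] == 2 && x["Hex"] <= 4) return("paucimannose")
  if (x["HexNAc"] == 3 && x["Hex"] >= 5) return("hybrid")
  if (x["HexNAc"] >= 4 || (x["HexNAc"] == 3 && x["Hex"] <= 4)) return("complex")
  "other"
}

#' @rdname classify_composition
#' @export
is_fucosylated <- function(c) as_counts(c)["dHex"] >= 1

#' @rdname classify_composition
#' @export
is_sialylated <- function(c) {
  x <- as_counts(c)
  (x["NeuAc"] + x["NeuGc"]) >= 1
}

#' Per-group glycan panel statistics
#'
#' A glycan counts as identified in a group when its intensity is observed
#' (non-missing) in at least one replicate column of that group.
#' Fucosylation and sialylation proportions are reported count-based (share
#' of identified glycans) and abundance-weighted (share of summed linear
#' intensity, `2^log2`).
#'
#' @param panel glycans x columns log2 intensity matrix (NA = not detected).
#' @param compositions named list of [glycan_composition()] (or NA for
#'   unassigned), covering the panel's rownames.
#' @param groups per-column group labels (default: column names).
#' @return A list: `per_group` (data.frame with n_identified, fucosylated
#'   and sialylated percentages, count- and abundance-based), `sets` (list
#'   of identified glycan ids per group), `venn` (pairwise data.frame with
#'   shared / exclusive counts), `classes` (group x class count table).
#' @export
group_stats <- function(panel, compositions, groups = colnames(panel)) {
  groups <- as.character(groups)
  if (length(groups) != ncol(panel)) stop("one group label per panel column")
  unassigned <- setdiff(rownames(panel), names(compositions))
  if (length(unassigned))
    stop("glycans without composition or unassigned flag: ",
         paste(utils::head(unassigned), collapse = ", "))
  glev <- unique(groups)
  comp_ok <- !vapply(compositions, function(x) length(x) == 1 && is.na(x), TRUE)
  fuc <- vapply(compositions[comp_ok], is_fucosylated, TRUE)
  sia <- vapply(compositions[comp_ok], is_sialylated, TRUE)
  cls <- vapply(compositions[comp_ok], classify_composition, "")
  sets <- list(); rows <- list(); class_tab <- list()
  for (g in glev) {
    sub <- panel[, groups == g, drop = FALSE]
    ident <- rownames(panel)[rowSums(!is.na(sub)) >= 1]
    sets[[g]] <- ident
    ia <- intersect(ident, names(fuc))  # identified and assigned
    inten <- 2^rowMeans(sub[ia, , drop = FALSE], na.rm = TRUE)
    rows[[g]] <- data.frame(
      group = g, n_identified = length(ident), n_assigned = length(ia),
      fuc_pct_count = 100 * mean(fuc[ia]),
      sia_pct_count = 100 * mean(sia[ia]),
      fuc_pct_abundance = 100 * sum(inten[fuc[ia]]) / sum(inten),
      sia_pct_abundance = 100 * sum(inten[sia[ia]]) / sum(inten),
      stringsAsFactors = FALSE)
    class_tab[[g]] <- table(factor(cls[ia], levels = c(
      "high_mannose", "paucimannose", "hybrid", "complex", "other")))
  }
  venn <- list()
  if (length(glev) > 1) {
    cmb <- utils::combn(glev, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      venn[[length(venn) + 1]] <- data.frame(
        group_a = a, group_b = b,
        shared = length(intersect(sets[[a]], sets[[b]])),
        only_a = length(setdiff(sets[[a]], sets[[b]])),
        only_b = length(setdiff(sets[[b]], sets[[a]])),
        stringsAsFactors = FALSE)
    }
  }
  list(per_group = do.call(rbind, rows), sets = sets,
       venn = if (length(venn)) do.call(rbind, venn) else NULL,
       classes = do.call(rbind, class_tab))
}

#' Differential glycan abundance
#'
#' Delegates to the proteome differential machinery on log2
#' median-normalized glycan intensities: per-group one-vs-rest t tests and
#' an across-group ANOVA.
#'
#' @param panel glycans x samples log2 intensity matrix.
#' @param groups per-sample group labels.
#' @param ... passed to [differential_table()].
#' @return A list: `anova` (from [anova_across()]), `tables` (per-group
#'   [differential_table()] results).
#' @export
differential_glycans <- function(panel, groups, ...) {
  m <- median_normalize_columns(panel)
  tables <- lapply(stats::setNames(nm = unique(as.character(groups))),
                   function(g) differential_table(m, groups, g, ...))
  list(anova = anova_across(m, groups), tables = tables)
}
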