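#' Simulate a glycan panel with known compositions
#'
#' Draws valid N-glycan compositions (core rules of the glycan module),
#' computes their exact permethylated-reduced neutral masses, perturbs the
#' observed masses with Gaussian ppm noise, and assigns group-specific
#' presence and log-normal intensities. Fucosylation and sialylation
#' fractions can be planted per group.
#'
#' @param n_groups number of sample groups.
#' @param compositions_per_group glycans present per group.
#' @param ppm_noise standard deviation of the mass error in ppm (>= 0).
#' @param seed integer RNG seed.
#' @param fuc_frac,sia_frac per-group planted fractions of fucosylated /
#'   sialylated compositions (recycled to `n_groups`).
#' @param end_group see [composition_mass()].
#' @return A list: `panel` (glycans x groups log2 intensity matrix, NA =
#'   absent), `observed_mass` (named vector), `truth` (named list of
#'   generating [glycan_composition()]s), `groups` (column labels).
#' @export
simulate_glycan_panel <- function(n_groups, compositions_per_group,
                                  ppm_noise = 3, seed = 1,
                                  fuc_frac = 0.6, sia_frac = 0.5,
                                  end_group = "reduced_permethylated") {
  if (ppm_noise < 0) stop("ppm_noise must be >= 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  fuc_frac <- rep_len(fuc_frac, n_groups)
  sia_frac <- rep_len(sia_frac, n_groups)
  glycans <- list(); keys <- character(0)
  membership <- list()
  for (g in seq_len(n_groups)) {
    n_fuc <- round(fuc_frac[g] * compositions_per_group)
    n_sia <- round(sia_frac[g] * compositions_per_group)
    want_fuc <- sample(rep(c(TRUE, FALSE),
                           c(n_fuc, compositions_per_group - n_fuc)))
    want_sia <- sample(rep(c(TRUE, FALSE),
                           c(n_sia, compositions_per_group - n_sia)))
    ids <- character(compositions_per_group)
    for (i in seq_len(compositions_per_group)) {
      for (try in 1:200) {
        cmp <- random_composition(want_fuc[i], want_sia[i])
        key <- format(cmp)
        # reuse an identical composition already in the panel; else add it
        if (!key %in% keys) { glycans[[key]] <- cmp; keys <- c(keys, key) }
        if (!key %in% ids) break
      }
      ids[i] <- key
    }
    membership[[g]] <- ids
  }
  exact <- vapply(glycans, composition_mass, 0, end_group = end_group)
  observed <- exact * (1 + stats::rnorm(length(exact), 0, ppm_noise) * 1e-6)
  names(observed) <- names(glycans)
  panel <- matrix(NA_real_, length(glycans), n_groups,
                  dimnames = list(names(glycans), paste0("G", seq_len(n_groups))))
  for (g in seq_len(n_groups)) {
    ids <- unique(membership[[g]])
    panel[ids, g] <- log2(stats::rlnorm(length(ids), meanlog = 20, sdlog = 1.5))
  }
  list(panel = panel, observed_mass = observed, truth = glycans,
       groups = colnames(panel))
}

random_composition <- function(fucosylated, sialylated) {
  hexnac <- sample(2:6, 1)
  hex <- sample(2:9, 1)
  dhex <- if (fucosylated) sample.int(min(2L, hexnac + 1L), 1) else 0L
  neuac <- if (sialylated && hexnac >= 2) sample.int(min(2L, hexnac - 1L), 1) else 0L
  if (sialylated && neuac == 0) neuac <- 1L
  glycan_composition(Hex = hex, HexNAc = hexnac, dHex = dhex, NeuAc = neuac)
}
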