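# medullomix

Proteome-led multiomic subtyping of medulloblastoma, as a tested, reusable R
pipeline. Medulloblastoma cohorts profiled by TMT proteomics arrive as
log2 abundance matrices with heavy missingness and plex-level batch
structure; their biology is read out jointly with DNA methylation arrays,
copy-number profiles, N-glycan panels and immunohistochemistry. medullomix
implements the computational procedures that connect these layers:

* **Harmonization** — per-sample median normalization, batch location/scale
  equalization over missingness-dissection blocks (no imputation), row mean
  centering, UniProt-keyed merging, inclusive validity filters, and
  z-score flagging of blood-contaminated samples.
* **Consensus subtypes** — subsampled consensus clustering (Ward / k-medoids
  over pairwise-complete Euclidean/Pearson/Spearman distances), model
  selection by the proportion of ambiguous clustering
  (PAC = fraction of consensus entries in the open interval (0.1, 0.9);
  argmin over k), a six-way metric × method cluster-certainty vote (0–6 per
  sample), and a stepwise k-means profile hierarchy for k = 2..6.
* **Biomarkers** — one-vs-rest Student t tests (p < 0.05, |log2FC| > 1.5,
  ≥30% observed per subtype), across-subtype ANOVA, and top-5 selection by
  combined p-value / mean-difference rank.
* **Conservation** — subtype-restricted Pearson correlation of protein
  abundance with own-gene CpG M-values (M = log2(β/(1−β)), pass at
  r > 0.7), conservation fractions, CpG positional distributions with a TSS
  aggregate, DMR aggregation (≥10 probes, gaps < 1000 nt) and tri-omic
  per-gene correlation.
* **Proteome CNV** — gene-level genomic signals from centered abundances,
  recursive binary segmentation (Welch t + Bonferroni; exact on noiseless
  piecewise-constant input), gain/loss calls at the inclusive |0.2| cutoff,
  arm-level group frequency profiles, and cross-platform (proteome vs
  methylome) arm correlation; SEG/BED I/O.
* **N-glycans** — permethylated-reduced monoisotopic masses from elemental
  formulas, bounded depth-first mass decomposition with biosynthetic rules,
  composition classes, and per-group identification / fucosylation /
  sialylation statistics.
* **DH-score** — digital Histo-score from RGB immunostains: tissue area by
  grayscale thresholding (luminance ≤ 241), H-DAB color deconvolution, bins
  [0,134] / [135,182] / [183,203], DH = 3·strong + 2·medium + 1·weak.
* **Synthetic cohorts** — `simulate_cohort()`, `simulate_glycan_panel()` and
  `simulate_stain_image()` generate all of the above with known ground
  truth (planted subtypes, batch effects, MCAR/MNAR missingness,
  subtype-restricted protein↔CpG coupling, attenuated arm-level CNV events,
  contaminated samples, exact stain bin counts), so the full pipeline runs
  and validates without deposited data.

## Worked example

```r
library(medullomix)

cfg <- cohort_config(n_samples = 120, n_proteins = 1500, k_subtypes = 6,
                     n_markers_per_subtype = 60, marker_shift = 1.5,
                     noise_sd = 1, n_batches = 4, missing_frac = 0.25,
                     seed = 11)
co <- simulate_cohort(cfg)

m <- median_normalize_columns(co$prot) |>
  dissect_and_adjust_batches("location") |>
  row_mean_center()

sweep <- pac_sweep(m, k_range = 2:12, n_resamples = 250, seed = 7)
round(sweep$pac_by_k, 3)
#>     2     3     4     5     6     7     8     9    10    11    12
#> 0.791 0.684 0.435 0.172 0.032 0.075 0.117 0.128 0.135 0.142 0.142
sweep$best_k
#> [1] 6

vote <- certainty_vote(m, k = 6)
median(vote$certainty)
#> [1] 6
adjusted_rand_index(vote$modal, co$truth$subtype)
#> [1] 0.979652
```

PAC bottoms out at the planted k = 6 (0.032, an order of magnitude below
its neighbors), the six metric × method runs agree on a median 6/6 samples,
and the modal assignment reproduces the planted subtypes almost perfectly
(ARI 0.98). The numbered scripts under `analysis/` run the full narrated
chain — simulation, harmonization (9/9 planted contaminated samples
flagged), consensus subtyping, marker panels (5/5 planted markers per
subtype in the top-5 selections), conservation (35.9% of proteins with a
passing own-gene CpG in the coupled subtype vs <1% elsewhere, planted 40%
in clusters of ~20 samples), copy number, glycans and DH-scores — writing
tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

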