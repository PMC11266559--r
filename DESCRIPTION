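Package: medullomix
Title: Multiomic Medulloblastoma Subtyping Pipeline with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reusable implementations of the computational procedures behind
    proteome-led multiomic subtyping of medulloblastoma: TMT proteome
    harmonization with missing values (median normalization, batch
    location/scale equalization over missingness-dissection blocks, row mean
    centering, UniProt-keyed merging, validity filters, blood-contamination
    flagging), consensus clustering with PAC model selection and a six-way
    cluster-certainty vote, stepwise k-means profile hierarchies, subtype
    differential-abundance testing with top-5 biomarker selection,
    subtype-restricted protein-CpG correlation conservation analysis with DMR
    aggregation and tri-omic per-gene correlation, proteome-derived copy-number
    inference (recursive binary segmentation, gain/loss calls at |0.2|, arm
    frequency profiles, cross-platform correlation), permethylated N-glycan
    mass decomposition and composition statistics, and digital Histo-score
    quantification of DAB immunostains. A synthetic multiomic cohort generator
    with known ground truth makes every analysis exercisable without deposited
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
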