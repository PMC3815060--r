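Package: lipidnet
Title: Condition-Dependent Multi-Omics Integration for Yeast Lipid
    Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates transcriptome, metabolome and lipidome profiles
    measured under a two-level three-factor chemostat design (carbon
    limitation, aerobicity, temperature). Provides per-feature factorial
    ANOVA, exhaustive gene-metabolite/lipid Pearson correlation testing
    with Bonferroni control, a metabolic-network neighborhood
    correlation-bias test (Mann-Whitney rank-sum of neighbor versus
    non-neighbor correlations on a bipartite metabolite-gene map),
    pathway-grouped bias tests, transcription-factor target enrichment,
    and a small flux balance analysis stage, together with a
    synthetic-data generator with planted ground truth and Cytoscape
    export of all networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
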