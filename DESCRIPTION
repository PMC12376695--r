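Package: botlife
Title: Life-Cycle Analysis of Self-Motile Epithelial Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the life cycle of self-motile
    multicellular spheroids (Anthrobots) built from human airway epithelial
    cells. Links per-frame segmentation output into spheroid lineages and
    detects merge events during the Matrigel growth phase; computes circular
    statistics of eversion trajectories (straightness and gyration indices,
    14-axis kinematic feature vectors); derives degradation metrics from area
    time courses; clusters phenotype feature matrices with standardization,
    PCA and Ward.D2 hierarchical clustering with rank-sum group comparisons;
    and stages bulk transcriptomes with counts-per-million filtering, trimmed
    mean of M-values (TMM) normalization, log fold changes, phylostratigraphic
    gene-age counting and morula-gene overlap. A synthetic-data module
    generates every input with planted ground truth (growth archetypes,
    correlated-random-walk motion modes, size-dependent decay, negative
    binomial counts with planted differential expression) so that each stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
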