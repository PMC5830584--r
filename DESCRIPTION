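Package: cortcat
Title: Voxel-Wise Encoding Models and Cortical Category Organization
Version: 0.1.0
Authors@R:
    person("cortcat", "developers", email = "cortcat@example.org", role = c("aut", "cre"))
Description: Tools for studying how object categories are organized in
    cortical responses through voxel-wise encoding models built on
    hierarchical (CNN-style) stimulus features. Provides a synthetic-data
    generator with planted category hierarchy and known ground truth,
    a feature pipeline (hemodynamic convolution, two-stage PCA reduction,
    single-layer ablation), ridge-regression encoding models with
    cross-validated regularization, block-permutation significance testing
    and Monte-Carlo noise ceilings, model-synthesized category maps with
    d-prime selectivity, representational similarity with signed-modularity
    clustering, taxonomy- and vector-based semantic similarity, and
    layer-wise contribution profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
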