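Package: hippomorph
Title: Slice-Wise Morphometry of Hippocampal Subfield Label Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry for histology-annotated hippocampal
    subfield label maps on high-resolution (postmortem) MRI. Implements
    slice-wise measurements along the hippocampal long axis: subfield
    appearance and disappearance detection with contiguity rules, head and
    total length measures, medial-lateral proportions of the subicular
    complex via medial-axis ribbon tracing, projection of CA subfields onto
    the SRLM band ("flashlight" relabeling), relative SUB-CA1 border
    position against medial anchor constructions, and digitation-relative
    CA3 localization. Includes a synthetic hippocampus phantom generator
    with exhaustive ground truth, and a cohort statistics layer
    (exact/approximate Mann-Whitney U, Spearman rank correlation, and
    per-family Benjamini-Hochberg FDR control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
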