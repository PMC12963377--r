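Package: laggr
Title: Lymphoid Aggregate Detection and Immune Statistics for Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects lymphoid aggregates in cell-resolved spatial
    transcriptomics data by chemokine co-occurrence (CCL19-positive cells
    near CXCL13-positive cells), density-based clustering, centroid
    merging, and buffered concave-hull polygon demarcation, independent of
    B-cell content. Computes downstream immune statistics over detected
    aggregates: the plasma-cell-to-B-cell ratio (PBR), compartment
    fractions and enrichment scores, per-aggregate T-cell subset
    densities, exhaustion log-ratios, and their associations via Spearman
    correlation and simple linear regression. Includes companion
    immunohistochemistry analyses on marker-centroid tables with a
    tumor-bed annotation, clinical endpoint summaries (RECIST best
    response, CA19-9 response, pathology proportions, Kaplan-Meier
    medians), and synthetic-data generators with full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    deldir,
    polyclip,
    jsonlite,
    survival,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
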