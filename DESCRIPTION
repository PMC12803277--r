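Package: duplexium
Title: Integration of Dual-Chemistry Imaging Spatial Transcriptomics Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for combining two sequential imaging-based spatial
    transcriptomics runs of the same tissue section that were decoded with
    different probe-panel chemistries (a small high-sensitivity custom panel
    and a large discovery panel). Provides landmark-based similarity/affine
    registration of the two runs' coordinate frames with iterative
    closest-point refinement, point-in-polygon re-assignment of transcripts
    to a shared cell segmentation, transcript- and cell-level quality-control
    filtering, construction of panel-tagged combined cell-by-gene count
    matrices with retention accounting, and cross-panel statistics
    (pseudobulk correlations, z-score sensitivity comparisons for genes
    targeted by both panels, per-gene cross-chemistry rank correlation,
    per-cell secreted-gene diversity, and cluster-label concordance). A
    synthetic dual-run generator with known ground truth makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
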