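Package: scportray
Title: Self-Organizing Map Portraits of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Portrays single-cell RNA-seq expression landscapes with
    self-organizing maps (SOM). Cells are downsampled to meta-cells by a
    three-step clustering, a rectangular SOM is trained on the gene
    profiles over meta-cells, co-expressed spot modules are extracted from
    the over-expression landscape, meta-gene values are upscaled back to
    single-cell resolution by per-unit support-vector regression, and
    cells are stratified by their module activation patterns (PATs).
    Includes marker-based cell typing, cell-cycle phase scoring with
    expression-matched control genes, Fisher-exact PAT enrichment, PAT
    flow graphs between cell groups, and a synthetic-data generator with
    planted co-expression modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    e1071,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
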