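Package: mechanoScreen
Title: Prize-Collecting Steiner Tree Inference of Force-Responsive
    Transcription Factors and Image-Based Screening Readouts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs tripartite Protein-TF-RNA regulatory networks from
    protein-protein interaction tables, TF-target annotations and
    differential-expression comparisons, and selects a parsimonious
    regulatory subnetwork by Prize-Collecting Steiner Tree (PCST)
    optimization.  Transcription factors are ranked by the number of
    differentially expressed targets they can regulate.  The package also
    implements the image-based screening readouts used to validate such
    regulators in 3D fibroblast spheroid cultures under compressive load:
    per-nucleus chromatin-compaction ratio (i80/i20), Otsu-thresholded
    heterochromatin focus detection with peripheral-fraction statistics,
    spheroid spread-area quantification, and group-level screen statistics
    (pooled-variance t tests, Tukey-style box summaries, significance
    stars).  Synthetic-data generators with full ground truth support
    benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    withr,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Transcription, GeneRegulation,
    CellBiology, Visualization
RoxygenNote: 7.3.3
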