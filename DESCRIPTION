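Package: synteny3d
Title: Comparative 3D Chromatin Architecture and Synteny-Break Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative analysis of 3D
    chromatin architecture across related plant genomes: normalization of
    binned Hi-C contact matrices (iterative correction and Poisson-regression
    covariate normalization), A/B compartment calling from observed/expected
    correlation eigenvectors, insulation-score TAD detection with
    boundary/body/interval partitioning, collinear synteny-block chaining and
    synteny-break derivation from homolog tables, shuffle-null and Fisher
    exact co-localization tests between breaks and architectural features,
    cross-species compartment-switch and conserved-TAD classification, and
    orthologous expression-divergence contrasts. A synthetic multi-species
    data generator with known rearrangement, compartment, TAD and expression
    ground truth makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
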