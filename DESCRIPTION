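Package: plastigap
Title: Species Delimitation Analytics for Plastome Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for delimiting closely related plant species from
    whole-plastome data: sliding-window nucleotide diversity, Hudson-style
    FST and island-model gene flow (Nm), Kimura 2-parameter and p-distance
    barcode-gap tests, neighbour-joining trees with bootstrap monophyly
    assessment, detection of the quadripartite LSC/IRb/SSC/IRa plastome
    architecture, and ecological niche-overlap statistics (Schoener's D,
    Warren's I) on habitat-suitability grids. Includes a synthetic-data
    generator producing species-structured alignments, toy circular
    plastomes with planted inverted repeats, and suitability-grid pairs
    with known overlap, so every estimator can be checked against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
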