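Package: cortiStar
Title: Quantification of Cellular Patterning and Density in the Organ of Corti
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the crystalline organization and density of
    hair cells and supporting cells in the developing organ of Corti from
    digitized cell-centroid tables. Implements the six-arm nearest-neighbor
    angular-sector ("star") statistic over 16 radial bins with per-sector
    group t-tests, cell density per 100 um of sensory epithelium with
    two-way ANOVA and Tukey post-hoc comparisons, and a synthetic epithelium
    generator that emulates control and disrupted (Etv4/5/1 triple-knockout
    -like) cochlear mosaics so the full pipeline is testable without imaging
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
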