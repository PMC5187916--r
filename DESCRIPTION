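Package: targetfish
Title: Ligand-Based Target Fishing and Enzyme Assay Analysis for
    Natural-Product Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A ligand-based in-silico target-fishing pipeline built on
    2-D pharmacophore descriptors (pharmacophoric fragments, feature-pair
    distance distributions, and their Shannon entropies), thresholded
    neighbor retrieval against an annotated compound-target library, and
    inverse-distance-weighted interpolation of neighbor affinities.
    Includes the companion enzyme-assay analysis: kinetic slopes from
    fluorescence traces, relative inhibition, four-parameter logistic
    IC50 fitting, and pIC50 conversion, plus synthetic-data generators
    (annotated analog-series libraries and simulated assay plates) so
    the whole workflow runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
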