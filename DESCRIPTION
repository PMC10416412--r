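Package: ctce3d
Title: Spatial Mapping of Intra-Tumor Heterogeneity from Cycling-Temperature
    Capillary Electrophoresis Electropherograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mutant allele fractions from cycling-temperature
    capillary electrophoresis (CTCE) electropherograms collected on laser
    capture microdissection (LCM) sampling grids, attaches binomial-style
    Wald confidence intervals with a normal-approximation screen, and maps
    the mutant-fraction field in space: per-plane circle maps and heatmaps,
    scattered-data 3D interpolation (natural-neighbor and linear barycentric
    over a Delaunay tetrahedralization), and isosurface extraction with
    PLY/OBJ mesh export and a self-contained interactive 3D HTML view. A
    synthetic-data module simulates clonal 3D mutant-fraction fields, LCM
    grid sampling, CTCE traces with wild-type, mutant, heteroduplex and
    single-strand peaks plus an internal standard, and sample dropout, so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    interp,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
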