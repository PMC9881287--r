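Package: spotgate
Title: Polygon Gating, Differential Testing and Overlay Rendering for
    Spatial Omics Spot Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for spatial omics spot tables: aligns
    tab-separated spot tables with tissue images through Visium-style
    scale factors, defines polygon gates with ImageJ/Fiji ROI CSV
    interchange, filters feature tables by gate membership, compares gate
    groups feature-by-feature with exact or tie-corrected Mann-Whitney U
    tests and Bonferroni correction (volcano-ready output), and renders
    feature or cluster overlays on the tissue image with gradient
    colormaps and value-driven opacity. Includes a synthetic dataset
    generator (hexagonal spot grid, planted region effects) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
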