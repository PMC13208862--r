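Package: bioprintqc
Title: Quantitative Print-Quality Benchmarking for Extrusion Bioprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolpath generation, volumetrically calibrated G-code export,
    synthetic deposition rendering, Fiji-style image segmentation, and the
    standard print-quality metric set (spreading ratio, uniformity ratio,
    printability index, collapse angle and apparent yield stress, filament
    fusion spacing, porosity and pore hydraulic radius) for benchmarking
    extrusion bioprinting systems, in particular pneumatic versus screw-driven
    volumetric extrusion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
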