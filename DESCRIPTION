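Package: curvmap
Title: Curvature-Domain Analysis for Intrinsic-Signal Optical Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intrinsic-signal optical imaging studies of
    curvature-selective functional domains in visual cortex. Renders
    ellipse-derived curvature gratings, straight gratings, flashed lines and
    scrambled controls; simulates imaging sessions over synthetic cortical
    architectures with planted orientation maps, color/orientation bands,
    curvature domains and pinwheels; computes per-pixel dR/R responses,
    paired-t difference maps and the band-pass spatial filtering used in the
    field; detects significant functional domains and their morphometrics;
    builds orientation angle maps and locates pinwheel centers; and quantifies
    map similarity, straight-to-curved domain progressions and domain-averaged
    response timecourses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
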