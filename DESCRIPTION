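Package: streakquant
Title: Single-Cell Immunofluorescence Quantification for Differentiating
    Stem-Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-cell quantification of multichannel fluorescence microscopy
    of differentiating human pluripotent stem-cell cultures: mean nuclear
    intensities of fate markers, DAPI-relative normalization, directional
    (ray-based) membrane-intensity profiling for cadherins, quadrant gating of
    co-expression scatter data, live-imaging channel registration by integer
    pixel shift, background subtraction and membrane/non-membrane intensity
    ratios over time, per-image median summarization with Welch t-tests and
    Bonferroni adjustment, and a synthetic microscopy-field generator that
    provides per-cell ground truth for benchmarking every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
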