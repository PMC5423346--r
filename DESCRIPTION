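Package: pcasl
Title: Pseudo-Continuous Arterial Spin Labeling Simulation, Quantification
    and Multi-Scanner Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative cerebral blood flow (CBF) mapping from
    pseudo-continuous arterial spin labeling (pCASL) acquisitions, aimed at
    intraoperative resection control. Implements the single post-labeling-
    delay consensus quantification equation, a digital head phantom and
    pCASL acquisition simulator for three scanner profiles (3T head coil,
    1.5T head coil, 1.5T intraoperative surface coils), label/control
    subtraction and gray-matter ROI extraction, cross-scanner agreement
    statistics (Pearson correlation, two-way intraclass correlation), and a
    reproducible z-score rating of residual tumor as elevated perfusion in a
    shell around a resection cavity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
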