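Package: ccfd
Title: Choriocapillaris Flow-Deficit Quantification from En Face OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow deficits on co-registered en face
    swept-source OCT angiography slabs of the central macula. Implements
    drusen-shadow compensation of the flow slab (invert, Gaussian-smooth and
    multiply by the structure slab), Phansalkar local adaptive thresholding
    over a circular window, 8-connected particle extraction with per-eye
    flow-deficit metrics (FD percentage, count, mean size, total area), and a
    window-radius sensitivity analysis. A cohort statistics layer provides
    group summaries, two-sided Fisher exact and Mann-Whitney comparisons, a
    log-log fit of flow-deficit size against count, and a univariate screen
    followed by multivariate linear regression. A synthetic-scene and
    synthetic-cohort generator with known ground truth supports end-to-end
    validation without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    tiff,
    png,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
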