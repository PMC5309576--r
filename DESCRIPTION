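Package: tidalagree
Title: Tidal Breathing Parameter Extraction and Between-Device Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for method-comparison studies of tidal breathing measured
    simultaneously by two devices, such as a pneumotachograph (flow/volume at
    the mouth) and a non-contact thoraco-abdominal displacement sensor.
    Includes a synthetic-data generator with analytic ground truth,
    shape-preserving resampling, zero-phase elliptic band-pass filtering and
    cross-correlation alignment, breath detection with artifact screening,
    the seven standard tidal indices (RR, tI, tE, tTot, tI/tE, tI/tTot, IE50),
    and agreement statistics: Bland-Altman limits of agreement, a
    repeated-measures variant with variance components, Wald tests of
    limit equality between sessions, post hoc power, and distribution
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    nortest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
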