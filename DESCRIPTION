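Package: clotsim
Title: Blood Clot Analogue Composition, CT Densitometry and Compressive
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how red blood cell (RBC) and platelet
    content drive the computed tomography (CT) and compressive mechanical
    characteristics of reconstituted blood clot analogues.  Computes
    PRP/RBC/PDP blending volumes for factorial clot recipes, extracts
    secant stiffness, hysteresis loss and plastic strain from cyclic
    compression traces, measures non-contrast CT density and
    contrast-enhanced density increase from Hounsfield-unit grids with a
    circular region-of-interest protocol, quantifies RBC/platelet content
    from labelled histology masks, and fits the simple and multiple
    least-squares regressions that decouple the two cellular
    contributions.  A seeded synthetic-data generator produces cohorts,
    cyclic stress-strain traces, CT phantoms and label masks with
    closed-form ground truth so that every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
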