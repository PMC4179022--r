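Package: voltkit
Title: Post-Acquisition Processing of Voltammetric and Amperometric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-acquisition processing of electroanalytical
    data: tolerant parsing of potentiostat ASCII exports (CHI, BASi, Autolab
    and generic multi-column XY text, including decimal-comma locales),
    voltammogram pretreatment (Savitzky-Golay smoothing, background
    subtraction, uncompensated-resistance and double-layer-capacitance
    correction, conversion to dimensionless form), derivative, integral,
    semiderivative and semiintegral (half-order Grünwald-Letnikov) transforms,
    the generalized elimination-voltammetry procedure for separating kinetic,
    diffusion and capacitive current components, and cursor-based evaluation
    of peaks and waves. A synthetic-signal module generates reversible cyclic
    voltammograms, component mixtures and instrument-dialect files so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
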