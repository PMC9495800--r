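Package: parafuzz
Title: Fuzzy-Logic Mapping of Temperature-Dependent Parasitoid Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mamdani fuzzy inference chain that predicts the
    temperature-dependent net reproductive rate (R0) of the larval
    endoparasitoid Dolichogenidea gelechiidivoris, a classical biological
    control agent of the tomato pinworm Tuta absoluta.  Provides trapezoidal
    membership functions, a three-rule max-min inference engine with centroid
    defuzzification, constrained least-squares calibration of membership
    breakpoints against laboratory temperature-R0 data, host-presence masking
    (habitat suitability above a probability threshold AND cropland), monthly
    raster application under current and temperature-shifted future climate
    scenarios, per-region performance-class pixel summaries, and a seeded
    synthetic-landscape generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
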