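Package: dendroiso
Title: Tree-Ring Stable-Isotope Chronologies and Climate Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building replication-gated stable carbon and oxygen
    isotope chronologies from per-tree cellulose series, removing the
    industrial-era atmospheric d13C (Suess) decline, screening monthly
    proxy-climate correlations, fitting and verifying linear transfer
    functions with dendroclimatological skill statistics (reduction of
    error, coefficient of efficiency, Durbin-Watson, Gleichlaeufigkeit),
    reconstructing climate with confidence bands, Hamming-window smoothing,
    sigma-threshold extreme-year detection, and matching cold extremes to a
    volcanic eruption catalog.  Includes a pseudoproxy generator with known
    ground truth so the full pipeline can be validated end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    signal,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
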