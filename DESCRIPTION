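Package: langmuir
Title: Analysis of Langmuir Monolayer Pressure-Area Isotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing Langmuir trough compression and
    compression-decompression experiments on amphiphile monolayers at the
    air/water interface. Reads time-ordered barrier traces, converts trough
    area to area per molecule and Wilhelmy wire force to surface pressure,
    splits multi-loop traces into hysteresis cycles, and extracts the
    standard isotherm descriptors: lift-off area, collapse point, the slope
    of the dynamic-rise region, the packing ratio chi, the in-plane
    compressibility modulus Cs^-1 = -A dpi/dA with phase-state
    classification, and the per-loop compression reversibility factor Rv.
    A seeded equation-of-state simulator generates isotherms and hysteresis
    loops with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
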