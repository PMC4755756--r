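Package: selenotrace
Title: Site-Specific Selenium Occupancies from Anomalous Difference Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies site-specific selenium occupancies at the belt-sulfur
    positions of nitrogenase-like metalloclusters from anomalous difference
    Fourier maps, using the 30 iron atoms of the two cofactor and two
    P-cluster copies as an internal anomalous-scattering reference.
    Includes a synthetic-scene generator that renders B-factor-smeared
    Gaussian peaks with planted occupancies onto crystallographic grids
    (CCP4/MRC mode-2 I/O), fixed-radius spherical density integration,
    calibrated occupancy estimation with residual-sulfur correction and a
    map-noise detection floor, turnover-normalized migration time-course
    assembly, and the surrounding enzyme kinetics (Dixon-plot inhibition
    constants, specific activities, lag phases, relative activities and
    dose optima).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
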