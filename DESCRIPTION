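Package: mmvital
Title: Seatbelt-Integrated Metasurface Radar Simulation and Vital-Sign
    Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and evaluation toolkit for a 60 GHz seatbelt-integrated
    transmitarray metasurface radar for in-car vital-sign monitoring.
    Computes hyperbolic focusing phase profiles and quantizes them to
    realizable unit cells, evaluates the focused beam by scalar
    angular-spectrum diffraction (focal profile, spot width, bending
    degradation) and layered-media matching by the transfer-matrix method,
    simulates FMCW slow-time baseband data for a chest displaced by
    respiration and heartbeat under standby, driving and bumpy vibration
    scenarios, extracts respiration and heart rates via range FFT, slow-time
    phase demodulation and variational mode decomposition, detects seat
    occupancy with an exponentially weighted moving-average variance
    statistic, and reports Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
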