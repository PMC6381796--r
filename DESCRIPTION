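Package: unwindr
Title: Simulation and Analysis of Helicase DNA-Unwinding Kinetics at Protein Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA unwinding by replicative helicases
    (such as CMG) at strand-specific protein barriers. Provides a stochastic
    per-molecule unwinding simulator with barrier mechanisms (permanent
    arrest, transparent bypass, duplex-stabilizing pause), the m-step
    sequential (Erlang) kinetic model for ensemble fluorescence unwinding
    curves with observed-rate fitting and barrier-induced delay estimation,
    a single-molecule trace-analysis pipeline (intensity calibration,
    completion detection, pause calling, rate estimation, pause-duration
    statistics, population summaries), and band-intensity arithmetic for gel
    densitometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
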