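Package: sheeppulse
Title: Coupled Intermittent Walks in Sheep Groups: Simulation, Rate Inference
    and Traveling-Pulse Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying collective motion of small sheep groups that
    alternate grazing (stopped) and walking bouts. Implements the double
    mimetic start/stop switching-rate model, an exact event-driven (Gillespie)
    stochastic simulator of coupled intermittent walkers on a line, the data
    pipeline that estimates imitation strengths and exponents from following
    latencies, a conservative upwind solver for the nonlocal kinetic density
    equations, the closed-form sech-squared traveling-pulse solution of the
    minimal model, and a synthetic field-track generator emulating 1-Hz
    group tracking data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
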