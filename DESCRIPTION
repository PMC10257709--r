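Package: oscflow
Title: Constriction Flow of Self-Propelled Disks with Oscillating Radii
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-element simulation of two-dimensional self-propelled
    soft disks whose radii oscillate actively while the particles flow
    through a narrow bottom constriction, together with the statistical
    toolkit needed to characterise the resulting intermittent discharge:
    flow-rate estimation with confidence intervals, Clauset-Shalizi-Newman
    power-law fits of inter-exit times, burst/clog decomposition and the
    flowing parameter, bulk contact observables, and parameter-sweep
    orchestration to locate the flow-rate resonance at the contact natural
    frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
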