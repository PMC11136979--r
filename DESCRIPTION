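Package: kinestep
Title: Simulation and Step-Kinetics Analysis of MINFLUX Kinesin Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the stepping kinetics of kinesin-1 from
    MINFLUX single-fluorophore tracking data. Includes a stochastic
    simulator of kinesin walking paths (paired substeps, exponential
    one-head-bound and two-head-bound dwells, microtubule switching) and
    of MINFLUX photon-count acquisition with the online position-update
    estimator; position refinement by a sliding curvature estimator;
    step detection by iterative change-point fitting with median
    filtering; hidden Markov annotation of bound and unbound states;
    maximum-likelihood dwell-time models; velocity, off-axis
    displacement and microtubule-switching analyses; and tabular
    trace and step table input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
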