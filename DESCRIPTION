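Package: itdisp
Title: Effective Dispersion and Pharmacokinetics of Intrathecal Drug Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for in-vitro intrathecal drug-dispersion
    experiments. Estimates the effective dispersion coefficient of a tracer
    in the spinal subarachnoid space from axial intensity time series by
    inversion of the one-dimensional parabolic diffusion equation (moment
    inversion) and by the classical method of moments; fits dimensional and
    dimensionless (Womersley/Peclet) correlations linking dispersion to
    cerebrospinal-fluid pulsation amplitude and frequency; estimates
    caudocranial drift velocities; and simulates a distributed
    six-compartment pharmacokinetic model with multi-dose schedules. A
    synthetic tracer-experiment generator reproduces the statistical
    structure of bench data (bounded-domain diffusion, caudocranial drift,
    injection phase, optical noise) so the full pipeline is testable without
    phantom video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
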