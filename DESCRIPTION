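Package: circph
Title: Lumped-Parameter Circulation Model with Progressive Pulmonary
    Hypertension Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter, electrical-analog)
    model of the human systemic and pulmonary circulation. Heart chambers are
    time-varying elastance elements blending end-systolic and end-diastolic
    pressure-volume relations through Gaussian-sum activation functions;
    vessels are Windkessel compartments with linear, logarithmic or piecewise
    pressure-volume laws; valves are ideal diodes in series with resistances.
    The circuit is integrated as a first-order ODE system with a fixed-step
    fourth-order Runge-Kutta scheme. Four time-progressive pulmonary
    hypertension scenarios (distal pulmonary artery stenosis, left ventricular
    diastolic dysfunction, ventricular septal defect, mitral stenosis) are
    driven by per-cycle parameter schedules. Read-outs include pressure
    waveforms, pressure-volume loops, systolic/diastolic/mean pressures,
    stroke volume, ejection fraction, cardiac output and mean pulmonary artery
    pressure, with CSV export and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
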