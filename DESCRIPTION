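Package: tmas
Title: Transcranial Magneto-Acoustical Stimulation of Hodgkin-Huxley Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation of transcranial magneto-acoustical
    stimulation (TMAS), in which focused ultrasound applied inside a static
    magnetic field induces a Lorentz-force electric current density in brain
    tissue.  The package converts acoustic intensity and magnetostatic field
    strength into a membrane current density, drives a Hodgkin-Huxley
    conductance-based neuron with continuous or pulsed ultrasound using a
    fixed-step fourth-order Runge-Kutta integrator, extracts firing-pattern
    statistics (spike amplitude, interspike interval, firing rate per
    stimulation cycle), locates the constant-current firing threshold by
    bisection, and computes the diagnostic-ultrasound mechanical and thermal
    safety indices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
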