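Package: lvddsim
Title: Closed-Loop Lumped-Parameter Hemodynamics of Left Ventricular
    Diastolic Dysfunction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A closed-loop lumped-parameter model of the human
    cardiovascular system with four heart chambers, an actively
    contracting interventricular septum solved by fixed-point iteration,
    a pericardial constraint, systemic and pulmonary vascular networks,
    baroreflex control, and pleural-pressure forcing.  Includes a
    scenario engine for left ventricular diastolic dysfunction (impaired
    relaxation, restrictive, pseudo-normal, restrictive with normal
    septum, augmented systolic contractility) and extractors for the
    clinical waveform indices used to phenotype diastolic function
    (E/A ratio, deceleration time, IVRT, venous D/S ratios, respiratory
    variation, pressure-volume loop analysis).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
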