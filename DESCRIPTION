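Package: corowave
Title: Integrated Coronary Perfusion Modelling and Wave Intensity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced-order model of coronary haemodynamics coupling a
    one-dimensional pulse-wave solver on a binary arterial tree to lumped
    poroelastic myocardial compartments and a contracting left ventricle
    with aortic valve dynamics and a three-element windkessel afterload.
    Includes a synthetic coronary tree generator matched to porcine
    morphometry, coronary wave intensity analysis (forward/backward
    separation, six-wave classification, cumulative percentage wave areas)
    and a parameter-perturbation harness for studying wave sensitivity to
    contractile, haemodynamic and valve parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
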