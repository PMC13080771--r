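Package: axicell
Title: Axisymmetric Finite-Element Analysis of Single-Cell Indentation into Soft Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear axisymmetric finite-element models of a single invasive
    cell indenting a soft elastic gel. A hemispherical cell with an embedded
    ellipsoidal nucleus is meshed conformingly onto a gel cylinder; compressible
    Neo-Hookean, Saint Venant-Kirchhoff and quasi-linear viscoelastic (Prony
    series) material laws are solved quasi-statically by Newton iteration with
    incremental loading. Self-equilibrated push-pull load cases route a central
    downward force through the top or bottom third of the nucleus, balanced by
    angled tractions at the cell perimeter. Post-processing computes indentation
    depth, von Mises and total (trace) stress aggregates per region,
    gel-transmitted stress and top-versus-bottom percentage differences, with
    parameter-sweep and mesh-convergence drivers plus analytic verification
    fixtures (flat punch, uniaxial patch, step-strain relaxation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Config/testthat/start-first: geometry, constitutive, loading, solver,
    postprocess, study
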