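Package: semfacets
Title: Meaning Facets of Computational Bio-Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A machine-readable data model for the intrinsic and extrinsic
    structure/function/behaviour semantics of kinetic bio-models, together
    with the executable machinery the framework presupposes: construction of
    the ODE programme from an SBML-subset reaction network, execution of
    simulation experiments described in a SED-ML-like subset, qualitative
    classification of model dynamics with TEDDY-style labels, two-parameter
    regime scans with Hopf-bifurcation boundary location, a declarative
    dynamics-assertion language (DYML) with a checker, and facet-based model
    comparison.  The two Tyson (1991) cell-cycle models of MPF activation are
    reconstructed programmatically as worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
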