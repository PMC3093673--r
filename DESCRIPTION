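Package: cleftflux
Title: Analytical Reaction-Diffusion Model of Ligand Flux in a Synaptic Cleft
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the time-dependent receptor-absorption flux J(t) of a
    ligand (acetylcholine in a neuromuscular junction, or Ca2+ in a dyadic
    cleft) released into a thin laterally periodic cleft between two
    membranes. The concentration field is expanded in a two-dimensional
    cosine series in Laplace space; the mixed boundary condition on the
    absorbing receptor disk is closed with the constant-flux approximation
    and the transform is inverted numerically by the Stehfest algorithm. An
    independent explicit finite-difference solver of the same boundary-value
    problem is included as a cross-check, together with closed-form
    calculators linking receptor number, size and reactivity to the model's
    sink parameters.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
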