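Package: cspff
Title: Crystal Structure Prediction with Fitted Intermolecular Pair Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rigid-molecule crystal structure prediction driven by
    analytic two-body force fields fitted to component-resolved dimer
    interaction energies.  Implements an extended atom-atom pair potential
    (polynomial-prefactored exponential repulsion, r^-12 wall, Tang-Toennies
    damped dispersion and electrostatics) alongside classical exp-6-1 and
    12-6-1 forms; a synthetic reference oracle standing in for quantum
    dimer calculations; a staged component-wise fitting protocol with
    hole/barrier safeguards; deterministic orientation-grid and two-step
    random crystal packing generators in standard space groups; Ewald-based
    periodic lattice energies with staged rigid-body minimization; polymorph
    clustering, ranking and cluster-overlap scoring against a reference
    crystal; and an iterative force-field refinement loop fed by
    nearest-neighbour dimers extracted from top-ranked polymorphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
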