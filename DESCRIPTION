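Package: cryptsim
Title: Individual-Cell-Based Model of Stem Cell and Tissue Organisation
    in the Intestinal Crypt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional, off-lattice, individual-cell-based model of the
    murine small-intestinal crypt. Cells are adhesive elastic spheres (Hertz
    contact, contact-area adhesion, bulk compression) moving with overdamped
    dynamics on a triangulated basal-membrane fibre network laid over a
    parametric crypt surface. Wnt activity follows the local surface curvature,
    Notch activity follows lateral cell-cell contacts, and both drive a
    reversible lineage state machine (undifferentiated, Paneth-, Goblet- and
    enterocyte-primed, and terminal fates) with stochastic Gamma-distributed
    growth, contact inhibition of growth, division and removal rules. The
    package ships the virtual experiments built on the model: steady-state
    turnover statistics, virtual BrdU pulse-chase sectioning, clonal labelling
    and monoclonal conversion, Wnt/Notch gain- and loss-of-function
    perturbations, subpopulation ablation, and parameter sweeps, together with
    a configuration layer and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
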