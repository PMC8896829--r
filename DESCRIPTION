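Package: furrowsim
Title: Energy-Minimization Vertex Model of Drosophila Ventral Furrow Formation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex model of the cross-section of a
    cellularizing Drosophila embryo, used to study the mechanics of ventral
    furrow formation. A ring of 80 wedge-shaped cells confined by a rigid
    vitelline shell is driven by Gaussian-weighted apical constriction in an
    18-cell mesoderm domain and by in-plane compression generated through
    apicobasal rest-length shortening of the ectoderm. Quasi-static furrow
    trajectories are obtained by minimizing a spring-and-area-penalty energy
    while the basal stiffness is lowered adiabatically. The package encodes
    in-silico optogenetic perturbation experiments (removal of contractility
    at intermediate equilibrium states, compression and lateral-force sweeps,
    constriction-domain perturbations) together with the tissue- and
    cell-level metrics used to read them out, in particular the invagination
    depth of the furrow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
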