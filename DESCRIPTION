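Package: rexdmd
Title: Replica-Exchange Discrete Molecular Dynamics for Helical
    Propensity Profiling of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven (discrete) molecular dynamics for coarse-grained
    four-bead polypeptide chains under stepwise square-well potentials, with
    Andersen-style thermostatting, temperature replica exchange, and the
    downstream conformational-ensemble analysis used to characterise
    intrinsically disordered proteins: phi/psi torsion profiles, per-residue
    alpha-helical propensities, per-frame continuous-helix maps, Ramachandran
    region occupancies, radius-of-gyration/energy density-of-states surfaces,
    and detection of transiently helical pre-structured motifs (PreSMos)
    against reference annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    seqinr,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
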