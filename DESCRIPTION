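Package: vasctherm
Title: 1D Vascular Network Modeling of Transarterial Thermoembolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one-dimensional vascular graphs from vessel-centerline
    NIfTI volumes, solves steady Hagen-Poiseuille network blood flow with
    lumped-conductance outflow boundaries, simulates advection-reaction
    transport of an acid-chloride/Lipiodol bolus, scores per-node cumulative
    hydrolysis damage to predict embolization sites, and calibrates the two
    free model parameters (terminal conductance and hydrolysis time constant)
    against weight-derived hepatic perfusion and observed embolization labels,
    with uncertainty grids, Pearson correlation summaries and leave-one-out
    cross-validation across subjects. Includes a synthetic bifurcating-tree
    generator so the full pipeline is testable without animal imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
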