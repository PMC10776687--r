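Package: gatekin
Title: Occlusion Gating Dynamics and Transport Kinetics of Neurotransmitter Transporters
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to distinguish transporter substrates from inhibitors by
    their conformational and kinetic signatures. Implements gate-distance
    featurization of structural ensembles, ligand-residue interaction energy
    descriptors, principal component and functional mode analysis, the
    tICA / k-means / Markov-state-model chain with implied-timescale,
    Chapman-Kolmogorov and bootstrap validation, Boltzmann free-energy
    surfaces over independent components, and the standard electrophysiology
    and uptake curve fits (mono-exponential relaxation, dose-dependent
    flipping rate, recovery, four-parameter logistic IC50, Michaelis-Menten,
    competitive/non-competitive classification). A synthetic-data module
    generates ground-truth-known surrogates: latent two-basin Langevin
    occlusion trajectories with observable emission, discrete Markov chains,
    and patch-clamp current traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
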