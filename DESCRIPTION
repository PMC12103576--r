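Package: sptkin
Title: Two-Color Single-Particle Tracking Colocalization Kinetics
Version: 0.1.0
Authors@R: person("Maintainer", "sptkin", email = "sptkin@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-color single-molecule trajectory data on the
    plasma membrane: inter-channel registration from bead fiducials, repair of
    dropout-split track segments, time-averaged mean squared displacement and
    diffusion-coefficient estimation, confined-diffusion classification,
    frame-wise two-channel colocalization with random-colocalization
    deconvolution (Lucy-Richardson) to estimate association and dissociation
    rate constants of reversible receptor-coreceptor binding, co-confinement
    versus co-diffusion classification of interaction events, stepwise
    photobleaching cluster sizing, and double-baseline correction of BRET
    kinetic plate-reader traces. Includes a ground-truthed stochastic
    simulator of reversible binding between two diffusing membrane species,
    used for validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
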