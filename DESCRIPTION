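Package: atcmdose
Title: Organ Dose Consequences of CT Localiser and Positioning Deviations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying how automatic tube current
    modulation (ATCM) in low-dose chest CT reacts to localiser projection
    angle, scan direction, and vertical or lateral off-centring, and what
    that does to organ-specific absorbed doses. Provides synthetic
    anthropomorphic voxel phantoms with organ masks, divergent fan-beam
    localiser projection, vendor-archetype tube current modulation models
    (including dual-localiser combination, NRMSE-based profile translation,
    and online feedback with angular lag), a voxel Monte Carlo photon
    transport engine with bowtie filtration and free-in-air kerma
    calibration, and the organ-dose statistics used to compare deviating
    setups against a reference scan (relative dose differences, paired t,
    repeated-measures ANOVA with Dunnett post hoc, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
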