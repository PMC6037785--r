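Package: kinetracer
Title: Simulation and Quantification of Single-Molecule Motor Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying minus-end-directed kinesin motility on
    microtubules from single-molecule TIRF data. Provides a seeded stochastic
    generator of motor-microtubule motility (diffusive and processive
    trajectories, cluster fluorescence intensities, stepwise photobleaching
    traces, rendered kymographs and TIRF-like image stacks, self-organization
    time-lapses), spot detection and 2D-Gaussian intensity fitting with local
    background correction, trajectory linking and mean-squared-displacement
    diffusion estimation, kymograph motility metrics (run length, velocity,
    end dwell, event frequency) with explicit inclusion and censoring rules,
    cumulative-distribution-function fitting with bootstrap confidence
    intervals, photobleaching step counting, and a field-contrast statistic
    for microtubule self-organization movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
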