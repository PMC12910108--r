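Package: smkinetics
Title: Single-Molecule Colocalization and FRET Kinetics of Polymerase-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-color single-molecule TIRF
    experiments that measure DNA polymerase binding to, and nucleotide
    incorporation at, a primer-template junction. Provides a ground-truth
    trajectory simulator with alternating-laser-excitation (ALEX)
    photophysics (shot noise, donor-to-acceptor leakage, direct acceptor
    excitation, gamma imbalance, single-step photobleaching), a minimal
    imaging pipeline (spot detection, channel registration, drift
    correction, background-corrected intensity extraction, two-color
    colocalization), FRET corrections, threshold-based event calling,
    exponential and Gaussian kinetic fitting (observed binding rate and
    plateau, bound dwell times, incorporation dwell times, FRET-change
    magnitude and its conversion to nucleotides incorporated), and bulk
    assay quantification (gel-lane species fractions and microscale
    thermophoresis binding isotherms with ligand depletion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
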