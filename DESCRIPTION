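Package: holehopr
Title: Trajectory Analysis and Electron-Transfer Theory for Tryptophan Hole Hopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing tryptophan-to-tryptophan hole hopping in
    photosensitized proteins from molecular-dynamics style trajectories:
    topology and multi-frame XYZ input, per-fragment charge/spin/coupling time
    series, conformer classification, proximal solvation statistics (proximal
    g(r) and coordination numbers), hydrogen-bond bridge detection, partitioned
    surface electrostatic potentials at scaled van der Waals surfaces,
    electron-transfer event detection and outcome classification, and a Marcus
    and Landau-Zener theory layer (activation barriers with adiabatic coupling
    corrections, adiabaticity parameters, rate and lifetime estimates). Includes
    a seeded two-state diabatic generator that emulates the statistical
    structure of QM/MM/MD outputs for testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
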