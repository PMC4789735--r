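Package: fourway
Title: Thermodynamics and Conformer Dynamics of DNA Four-Way Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of coarse-grained DNA four-way (Holliday) junction
    trajectories and UV melting data. Builds the three-site-per-nucleotide
    representation of a four-strand junction, fits two-state tetramolecular
    melting curves with the van't Hoff relation to extract melting enthalpy,
    entropy and melting temperature, computes Debye-Hueckel screening lengths,
    classifies frames into open, iso-I and iso-II conformers from inter-base
    distances at the junction core, estimates ensemble conformer populations
    and transition probabilities, and measures inter-duplex angles. Includes
    a synthetic trajectory and melting-data generator (continuous-time Markov
    chain over conformers plus geometric rendering) for validation, readers
    and writers for extended-XYZ and LAMMPS dump trajectories, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
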