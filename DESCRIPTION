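Package: RedoxPMM
Title: Perturbed Matrix Method Redox Thermodynamics for Solvated Chromophores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds and diagonalizes the electrostatically perturbed electronic
    Hamiltonian of a quantum center (a chromophore such as a DNA nucleobase)
    along ensembles of classical point-charge configurations, and derives
    vertical and adiabatic ionization energies, oxidation free energies and
    standard reduction potentials from the resulting energy-gap series via the
    linear-response mean-of-bounds estimator. Includes readers for GRO-style
    coordinate series and a self-contained XYZQ dialect, block-averaged
    statistical errors, a solvent-truncation convergence scan, and a synthetic
    data generator (rigid water-like point-charge solvent sampled iid or by
    Metropolis Monte Carlo) so every stage is testable without external
    electronic-structure or molecular-dynamics inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
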