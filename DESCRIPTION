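Package: tuneRSH
Title: Solvated Gamma-Tuning of Range-Separated Hybrid Functionals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backend-agnostic toolkit for optimally tuning the range-separation
    parameter of range-separated hybrid (RSH) density functionals in implicit
    solvent. Implements the gas-phase (GP), partial-vertical (PV) and
    strict-vertical (SV) tuning schemes with fast/slow polarization-charge
    partitioning, the Koopmans residual J^2(gamma) loss with a two-round grid
    search, the screened-RSH (SRSH) beta rule, delocalization-error fractional
    charge curves, one-particle-picture diagnostics via Hirshfeld populations,
    charge-transfer asymptote references with dielectric screening, and UV/Vis
    spectral convolution with peak-assignment and benchmark error statistics.
    Quantum-mechanical inputs arrive through a narrow engine contract; an
    analytic mock engine makes every stage testable without an
    electronic-structure code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io-cube.R'
    'solvents.R'
    'spectra.R'
    'ct.R'
    'diagnostics.R'
    'pcm.R'
    'engine-mock.R'
    'tuning.R'
    'cli.R'
    'io-xyz.R'
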