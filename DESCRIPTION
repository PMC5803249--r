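Package: torsionPES
Title: Correlated Dihedral Potentials for Intramolecular Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parameterizes and evaluates intramolecular dihedral (torsion)
    potentials for flexible organic molecules. Implements the standard
    uncorrelated force field (per-angle Fourier series or tabulated profiles
    fitted from independent torsion scans) alongside a correlated,
    machine-learned alternative: an ensemble of logistic-hidden-layer neural
    networks trained on Fourier-encoded dihedral configurations that captures
    the angle-angle couplings an additive force field cannot. Includes rigid
    fragment conformer geometry with clash detection, a fast low/high-energy
    classification ensemble, a classifier-gated Metropolis Monte Carlo sampler
    over dihedral space, a tunable synthetic correlated potential energy
    surface that stands in for a quantum-chemistry oracle, and a benchmark
    harness comparing all models on a common test split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
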