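Package: fomotor
Title: Hybrid Monte Carlo / Brownian Dynamics Simulation of Proton-Driven
    c-Ring Rotation in the Fo Motor of ATP Synthase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulator of the membrane-embedded Fo motor of
    ATP synthase. Couples constant-pH-style Metropolis Monte Carlo sampling
    of glutamate protonation states (10 c-ring proton carriers plus the two
    half-channel glutamates) to overdamped Langevin rotation of the c-ring
    on the resulting electrostatic energy surface. Includes an idealized
    synthetic geometry generator, Calpha-based geometry extraction from
    PDB/mmCIF structures, proton-motive-force energetics (pH gradient,
    membrane potential, intrinsic pKa), distance/angle-gated proton-transfer
    kinetics with the conserved-arginine leakage gate, mutant models
    (arginine-to-alanine, carrier Glu-to-Asp), trajectory analysis
    (rotation/flux coupling, deprotonation occupancy, leak detection,
    four-phase cycle decomposition), free-energy surfaces along the rotary
    angle, and a Bennett acceptance ratio free-energy estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
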