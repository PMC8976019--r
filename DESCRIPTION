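Package: kvcoupling
Title: Voltage-Sensor/Pore Coupling Statistics for Ion Channel
    Trajectory Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory statistics for quantifying electro-mechanical
    coupling in voltage-gated ion channels: Kabsch superposition, RMSD
    series, per-residue RMSF, dynamic cross-correlation matrices (DCCM),
    replicate averaging and condition-difference (delta) matrices, and
    ligand-residue contact persistence, together with Boltzmann
    conductance-voltage, biexponential gating-kinetics and Hill
    dose-response fitting for two-electrode voltage-clamp recordings.
    Includes generators for correlated-motion synthetic trajectories and
    protocol-aware synthetic current traces so that every statistic is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
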