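Package: solvbox
Title: Solvent-Box Adequacy Diagnostics for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for deciding whether the periodic water box of a
    molecular dynamics simulation is large enough for the solvent to behave
    like bulk water. Implements mean-squared-displacement estimation of the
    water self-diffusion coefficient with the Yeh-Hummer finite-size
    correction, water-water hydrogen-bond network statistics under
    donor-acceptor distance cutoffs, Kabsch superposition and residue-pair
    distance time series with penalized binary-segmentation change-point
    detection of quaternary transitions, radial distribution functions and
    solvent density profiles around a solute, and a combined box-size
    adequacy report. Ships seeded synthetic-trajectory generators (Brownian
    water, ideal gas, hydrogen-bond lattices, layered hydration shells,
    piecewise-constant transition traces) with exactly known ground truth so
    every analysis stage is testable without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
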