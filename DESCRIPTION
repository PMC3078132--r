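Package: pentadyn
Title: Trajectory Descriptors and Two-State Dynamics for Membrane-Protein
    Pentamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of the
    phospholamban pentamer and similar bitopic membrane proteins. Computes the
    cytoplasmic-domain tilt angle relative to the lipid bilayer and the
    centroid distance from the bilayer midplane, Kabsch-superposed RMSD and
    per-residue RMSF profiles, moving-block bootstrap confidence estimates for
    autocorrelated orientation series (including two-level resampling across
    independent trajectories), and hysteresis-based segmentation of frames
    into extended ("R") and bent ("L") conformational states with transition
    and dwell-time detection. Includes a synthetic coarse-grained pentamer
    trajectory generator with Markov-switching Ornstein-Uhlenbeck orientation
    dynamics and planted ground truth, so the full pipeline is testable
    without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
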