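Package: halfchannel
Title: Proton Half-Channel Hydration and Hydrogen-Bond Chain Analysis for
    Membrane-Protein MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of proton half-channel integrity in the
    membrane-embedded a-subunit of bacterial F1Fo-ATP synthase.  Reads
    multi-model PDB and CHARMM DCD trajectories, quantifies structural
    water clusters (occupancy, capacity distributions, count time series),
    builds per-frame hydrogen-bond graphs over polar side-chain atoms and
    water oxygens, and decides whether a source-to-sink proton transfer
    chain is preserved or interrupted in each mutant system.  Includes a
    conformational-stability battery (Kabsch RMSD, RMSF, radius of
    gyration, Shrake-Rupley solvent-accessible surface area, intramolecular
    hydrogen-bond counts), side-chain stable-spatial-position
    classification, gate-contact statistics, membrane composition
    bookkeeping, and a synthetic toy-system generator that produces
    trajectories with known ground truth so every analysis stage is
    testable without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    cluster,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
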