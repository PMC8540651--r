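Package: premode
Title: Binding-Mode Evaluation and Forecasting for Covalent TRPA1 Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for covalent and prerequisite (pre-covalent,
    reversible) binding modes of electrophilic agonists of the TRPA1 ion
    channel. Provides pose-level metrics (heavy-atom RMSD in the fixed target
    frame, warhead-to-cysteine distance, 3.5 Angstrom binding-pocket residue
    matching, ligand efficiency per heavy atom), physics-based rescoring with
    AutoDock-style and FITTED-style free-energy functions sharing a
    Lennard-Jones 12-6 kernel with combining rules, energy-sorted 2 Angstrom
    pose clustering and rank labelling, per-residue Lennard-Jones interaction
    profiling of trajectories, loop-gating distance analysis with open/closed
    classification, binding/unbinding event detection, a threshold-based
    forecast of potent agonists, and deterministic synthetic fixtures (toy
    pockets, pose ensembles with prescribed RMSD, scripted trajectories) for
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
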