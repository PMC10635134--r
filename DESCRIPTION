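Package: NOEDock
Title: NOE-Restraint-Guided Ensemble Docking with Weighted-Ensemble Cavity
    Sampling
Version: 0.1.0
Authors@R: person("Morgan", "Reyes", email = "morgan.reyes@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for locating small-molecule binding modes in
    protein internal cavities from sparse NMR data. Calibrates qualitative
    NOESY cross-peak intensities into interproton distance restraints, extends
    them to heavy-atom bounds, derives docking-active residues, samples cavity
    opening with a weighted-ensemble resampler over a solvent-accessible
    surface area progress coordinate, selects receptor conformations by
    quality-threshold clustering, performs restraint-guided rigid-body docking,
    and filters poses by symmetry-aware RMSD clustering, top-k score ranking
    and NOE-violation thresholds. Ships a synthetic-complex generator with
    known ground truth so every stage is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'structure-io.R'
    'sasa.R'
    'restraints.R'
    'restraint-io.R'
    'we.R'
    'ensemble.R'
    'docking.R'
    'selection.R'
    'synthetic.R'
    'pipeline.R'
    'NOEDock-package.R'
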