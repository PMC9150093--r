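Package: membraneTools
Title: Quantitative Analysis of Lipid Bilayer Molecular-Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    lipid bilayers, optionally carrying a protein aggregate near the membrane
    surface. Computes the membrane bending modulus from the Boltzmann
    statistics of lipid splay angles, the area compressibility modulus from
    equilibrium area-per-lipid fluctuations, lateral lipid diffusion
    coefficients from mean-square displacements, acyl-chain deuterium order
    parameters, lateral density/thickness maps and radial distribution
    functions, protein-membrane proximity and contact statistics,
    cutoff-based nonbonded interaction energies, and surface packing defects
    ("cracks") detected on a van der Waals occupancy grid. A synthetic-data
    module generates bilayer fixtures with known ground-truth parameters so
    that every estimator can be validated without running any simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'lipid-definitions.R'
    'io.R'
    'traj-model.R'
    'synthetic.R'
    'elasticity.R'
    'dynamics.R'
    'spatial-maps.R'
    'proximity-energy.R'
    'cracks.R'
    'pipeline.R'
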