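Package: memBAR
Title: Membrane Interaction and Geometry Analysis for BAR Domain Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how BAR (Bin/Amphiphysin/Rvs) domain dimers bind and
    curve lipid bilayers, from molecular-dynamics style coordinate data.
    Provides readers for PDB and GRO structures and a plain-text frame-table
    trajectory interchange format; static structural geometry of the dimer
    (helix axes and inter-helix angles, principal-axis extent, Shrake-Rupley
    solvent-accessible surface area, buried dimer-interface area and
    interface hydrogen bonds); residue-lipid contact detection under periodic
    boundaries with the normalized longest-run occupancy statistic;
    protein-centered 2D lipid density maps; leaflet height and curvature
    profiles binned along the membrane long axis; and concave-angle dynamics
    of the dimer. A seeded synthetic-data module generates banana-shaped
    dimers, mixed-composition point-lipid bilayers with prescribed height
    fields, and scripted trajectories with known ground truth, so that every
    analysis stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'conformation.R'
    'contacts.R'
    'geometry.R'
    'hbonds.R'
    'io.R'
    'lipids.R'
    'membrane.R'
    'pipeline.R'
    'sasa.R'
    'synthetic.R'
    'zzz.R'
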