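Package: pethydro
Title: Structure-Function Analysis of PET-Degrading Polyester Hydrolases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of polyester
    hydrolases that degrade polyethylene terephthalate (PET). Covers
    crystal-structure geometry analysis (pi-stacking geometry, carboxylate
    out-of-plane rotation, chain-averaged C-alpha RMSD between homologs,
    metal-coordination shells), symmetry-corrected RMSD and Ward.D2
    clustering of docking-pose ensembles with per-residue binding-energy
    statistics, supermolecular interaction-energy bookkeeping over
    externally computed quantum-chemical energies, and an impedance
    spectroscopy pipeline that converts Randles-circuit capacitance fits
    of a thinning dielectric PET film into enzymatic degradation rates
    with group statistics. Includes synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr
Config/testthat/edition: 3
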