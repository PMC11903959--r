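Package: mdfluct
Title: Distance-Fluctuation and Mechanical-Connectivity Analysis of
    Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular dynamics ensembles of multi-chain
    proteins: assembly of superposed meta-trajectories from replica
    simulations, Calpha distance-fluctuation (DF) matrices, the local
    fluctuation (LF) coordination threshold, per-residue mechanical
    connectivity indices, mutant-versus-wild-type difference maps and
    column projections, together with supporting per-residue descriptors
    (backbone RMSF, hydrogen-bond occupancy, eight-class secondary
    structure frequencies, relative solvent accessibility).  Includes a
    Gaussian-network synthetic trajectory generator so that every analysis
    stage can be exercised and validated without external trajectory data,
    plus readers and writers for PDB and DCD files and a reproducible
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
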