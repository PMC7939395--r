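Package: cartwheel
Title: Pharmacophore Screening and NMR Analysis of SAS-6 Head-Domain
    Dimerization Inhibitors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for discovering small-molecule
    inhibitors of protein-protein interfaces, built around the SAS-6
    head-domain dimerization site that templates centriole assembly.
    Derives structure-based pharmacophore models from a dimer interface,
    enumerates feature sub-models with a mandatory core, rigid-body fits
    multi-conformer ligand libraries with exclusion volumes and ranks
    hits; filters chemical libraries by molecular properties and Tanimoto
    diversity; quantifies NMR chemical-shift perturbations from paired
    HSQC peak lists, classifies notable residues, fits fast-exchange 1:1
    titrations for Kd and maps perturbations onto structures; and
    analyzes protein-ligand trajectory frames for pose stability,
    hydrogen-bond occupancy and normalized ligand-residue contact maps.
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    ChemmineR,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
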