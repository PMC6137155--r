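Package: stdepitope
Title: Group Epitope Mapping from STD-NMR with Docking Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies saturation-transfer difference (STD) NMR effects per
    ligand proton, builds group epitope maps with absolute and relative STD
    percentages and colour-coded epitope classes, catalogues protein-ligand
    contacts (hydrogen bonds, hydrophobic contacts, cation-pi interactions)
    from complex coordinates, clusters conformer ensembles by pairwise RMSD
    into representative structures with open/closed state assignment, and
    scores rank concordance between NMR epitopes and in-silico contact maps.
    Includes a synthetic-data generator that emulates ligand-observed NMR
    screening panels and two-state conformer ensembles with planted ground
    truth, so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
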