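Package: evcomplexr
Title: Inter-Protein Evolutionary Couplings from Genome-Paired Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers co-evolving residue pairs between two interacting
    proteins from the evolutionary sequence record. Homolog pairs are
    matched within each species by genomic proximity and concatenated, a
    global Potts model is fitted to the paired alignment by
    pseudolikelihood maximization, and inter-protein couplings are
    normalized into the scale-free EVcomplex score used to call contacts
    across the interface and to classify subunit pairs as interacting.
    Includes evaluation of predicted contacts against experimental 3D
    structures, export of CNS/HADDOCK distance restraints for docking,
    and a synthetic-data module that samples alignments from Potts models
    with planted inter-protein couplings for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
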