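Package: phylowave
Title: Phylogroup-Aware Analysis of Protein Family Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how protein families diversify across an ordered
    succession of phylogroups, modelled on the evolution of the Slc11/Nramp/MntH
    family of proton-coupled manganese transporters. Provides identity-tier
    curation of sequence sets (greedy representative selection under a pairwise
    identity threshold), construction of group-specific sequence logos and
    PROSITE-verbose patterns with iterative refinement and taxonomic profiling
    of pattern hits, detection of type I and type II evolutionary rate-shift
    sites between groups with a permutation null and false discovery rate
    control, tracing of the fixation stage of conserved residues along an
    ordered phylogroup succession, mapping of coevolved site collections onto
    residue contact networks built from paired carrier conformations,
    Kabsch superposition and classical multidimensional scaling of conformer
    ensembles, and hydropathy-based counting of transmembrane segments.
    A seeded synthetic-data module generates grouped alignments, scan
    databases, membrane topologies and paired helical structures with planted
    ground truth so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
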