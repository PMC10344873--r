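Package: kstarscan
Title: Ensemble-Based Scanning of Interface Mutations for Binding Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Saturation scanning of protein-protein and protein-DNA binding
    interfaces with an ensemble-based K* binding score. Reads a two-partner
    complex from PDB, detects interface residues, trims to a shell around the
    interface, enumerates all allowed point mutations (histidine in three
    protonation states), builds discrete-rotamer conformation spaces for the
    complex and each unbound partner, computes pairwise-decomposed energy
    matrices, and evaluates epsilon-bounded partition functions to obtain
    Log10 K* scores and mutant-vs-wildtype differences. Mutations that lower
    the score by more than a configurable cutoff are classified as
    binding-disrupting, residue positions are ranked into mutational
    hotspots, and cancer-type-specific relative probabilities of mutation
    formation are computed from trinucleotide-context mutational signatures
    and the gene's coding sequence.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
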