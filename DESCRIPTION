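Package: flavocompare
Title: Comparative Structural Analysis of FAD/NADH-Dependent Oxidoreductases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structure and sequence analysis of
    flavoprotein oxidoreductases (apoptosis-inducing factor, type II NADH
    dehydrogenases, lipoamide dehydrogenase relatives and their homologs).
    Provides PDB/mmCIF structure handling, sequence-alignment-guided
    rigid-body superposition with iterative outlier rejection, distance-based
    cofactor binding-region extraction, superposition-based ligand transfer
    across homologs to predict unobserved binding regions, protein-partner
    interface detection, electron-tunneling distance audits, conserved-motif
    detection in multiple sequence alignments with structure mapping,
    homology-hit filtering, neighbour-joining trees with bootstrap support
    for family clustering, and deterministic synthetic-data generators for
    closed-loop testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
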