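Package: motifshift
Title: Reference-Anchored Motif Evolution Analysis for Ortholog Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Comparative analysis of short functional motifs across ortholog
    protein families: reference-anchored extraction of annotated regions
    (nuclear export signals, serine-rich regions, DNA-binding-domain
    signature motifs) by optimal pairwise alignment and coordinate lifting,
    enumeration of nuclear-export-signal consensus matches, per-column
    conservation profiles and sequence-logo data, clade-wise signature-motif
    tallies with parsimony-inferred substitution histories on a taxonomy,
    interface-residue conservation checks, and confidence-filtered rigid
    structural superposition. Includes a seeded ortholog-family simulator
    with planted motif transitions so every stage is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
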