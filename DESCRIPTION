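Package: ahepipe
Title: Anchored Hybrid Enrichment Locus Assembly, Orthology Assignment and
    Node-Support Rarefaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and analysis chain for anchored hybrid enrichment
    (AHE) phylogenomic data in teleost fishes and other clades affected by
    ancient genome duplication. Implements seed-and-extend majority-rule
    consensus assembly of capture reads, a greedy "paralog picker" that
    partitions per-individual consensus sequences into putatively
    orthologous homolog sets, alignment curation (missing-species, length
    and end-trimming filters, distance- and branch-length-based outlier
    removal, reading-frame enforcement), supermatrix concatenation with
    codon-aware partition schemes and matrix-completeness statistics, a
    distance-based bootstrap tree-support backend, and rarefaction curves
    of node support versus number of sampled loci. A synthetic-data module
    simulates species trees, duplication/loss gene families, in-frame
    sequences and probe-centred capture reads with known truth, so the
    whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
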