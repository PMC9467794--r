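Package: cubtools
Title: Codon Usage Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R:
    person("cubtools", "maintainers", email = "cubtools@example.org",
           role = c("aut", "cre"))
Description: Analysis of codon usage bias (CUB) in protein-coding sequences:
    positional nucleotide composition (GC3s, GC12 and per-base third-position
    fractions), relative synonymous codon usage (RSCU) with cross-species
    averaging, the effective number of codons (ENC) and the adaptation indices
    CAI, FOP and CBI, parity-rule-2 (PR2) coordinates, neutrality regression of
    GC12 on GC3s, classification of genes against the expected ENC-GC3s curve,
    hierarchical clustering of species by RSCU profiles, and distance-based
    neighbor-joining trees with Newick output. A deterministic synthetic-CDS
    generator with controlled mutational GC3 pressure, selection on optimal
    codons and inter-species divergence makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
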