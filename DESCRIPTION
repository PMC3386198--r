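Package: paleofoam
Title: Paleovirology of Endogenous Foamy-Like Viral Elements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing endogenous foamy-like retroviral elements
    ("molecular fossils") in vertebrate genomes: consensus genome
    reconstruction from fragmented germline copies, annotation of coding
    defects (in-frame stop codons, frameshift indels), grouping of copies
    into segmental-duplication sets by shared flanking sequence, Kimura
    two-parameter distances with variance, neutral-clock dating of germline
    invasion from duplicate divergence (t = d/2r), UPGMA-based dating of
    multi-copy duplication sets with bootstrap uncertainty, host-virus
    cophylogeny analysis (midpoint rooting, topology-congruence mapping,
    branch-pair regression with permutation test), and a seeded simulator
    of endogenization and codivergence for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
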