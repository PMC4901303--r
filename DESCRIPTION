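Package: baculokit
Title: Annotation, Comparative Genomics and Phylogenomics of Circular
    Baculovirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational workflow behind a baculovirus
    genome project: wrap-aware open reading frame (ORF) calling and naming
    on circular double-stranded DNA genomes, discovery of homologous
    regions (hrs) as clusters of imperfect ~38-bp palindromic repeats with
    per-locus consensus building and in silico PCR confirmation, promoter
    motif screening in fixed upstream windows, in silico restriction
    digestion with fragment-profile comparison, reciprocal-best-hit
    orthology with Karlin-Altschul E-values, synteny and inversion
    mapping via signed permutations, an hr-proximity permutation test for
    unique ORFs, and core-gene supermatrix phylogenomics (Poisson/JTT
    pruning likelihood, neighbor-joining with bootstrap, and a
    constrained-placement log-likelihood comparison). A synthetic-genome
    generator with truth tracking makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
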