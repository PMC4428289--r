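Package: crisprscape
Title: Comparative Characterization of CRISPR-Cas Systems in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of CRISPR-Cas systems in
    draft and finished bacterial genome assemblies, developed around the
    cyanobacterium Microcystis aeruginosa. Detects CRISPR arrays de novo by
    k-mer seeded repeat chaining, clusters direct repeats into families with
    strand canonicalization, assigns cas-operon subtypes (I-A, I-D, III-A,
    III-B) from annotated gene neighborhoods, searches spacers against
    mobile-element databases to find proto-spacers and infer PAM profiles,
    and provides a comparative-genomics layer: reciprocal-best-hit orthology
    under the 50/50 rule, Markov clustering into gene families, core/pan-genome
    rarefaction, shared-family matrices, fragment-based average nucleotide
    identity (ANI) and tetranucleotide z-score correlation (TETRA). Ships a
    synthetic-genome generator with ground-truth manifests so every stage has
    planted-truth tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
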