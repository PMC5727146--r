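Package: ksage
Title: Ks Age Distributions, Whole-Genome Duplication Detection, and
    Selection Screens from Comparative Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution analysis of coding
    sequences from two or three closely related species: open reading frame
    selection from transcript sets, all-vs-all protein similarity and Markov
    clustering into orthogroups, extraction of one-to-one ortholog and
    within-species paralog pairs, Nei-Gojobori estimation of synonymous (Ks)
    and nonsynonymous (Ka) substitution rates with Jukes-Cantor correction
    and Fisher's exact significance, log-Gaussian mixture modelling of Ks
    age distributions to locate speciation and polyploidy peaks, molecular
    clock dating of those peaks, and a Ka/Ks screen for positively selected
    gene pairs.  A codon-level simulator with planted divergence and
    whole-genome duplication events provides ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
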