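Package: hdrquant
Title: Quantification of CRISPR Knock-In Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating homology-directed repair (HDR)
    knock-in experiments read out by deep amplicon sequencing. Models a
    reference locus (amplicon, CDS window, guide RNA and PAM), builds
    single-stranded donor templates with homology arms, silent PAM/seed
    mutations and synonymous "Coding-bar" restriction sites, merges
    overlapping read pairs, aligns merged reads globally to the reference,
    and classifies every read as WT, Correct_HDR, Incorrect_HDR or Others
    using exact guide-window pattern matching with a protein-level synonymy
    check. Includes in-silico restriction genotyping of pooled samples and a
    seeded synthetic read generator with truth tables so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
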