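Package: clockdiv
Title: Relative Evolutionary Rates of Insect Circadian Clock Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for measuring lineage-specific divergence of
    circadian clock proteins across insect taxa. Assigns clock-gene orthologs
    from a transcriptome-like sequence set (with paralog disambiguation via
    rooted gene trees), trims alignments to conserved blocks, selects empirical
    amino-acid substitution models by AIC, builds gene trees (neighbor joining
    on maximum-likelihood pairwise distances with optional ML branch-length
    refinement), derives patristic distance matrices, computes a per-gene
    relative-rate statistic for a focal lineage, and compares the core
    transcription-translation feedback-loop (TTFL) genes against the
    post-translational modifier (PTM) genes. A synthetic-data generator
    simulates seven-taxon clock-gene studies with known ground truth so every
    stage is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
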