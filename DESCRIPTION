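Package: vertconn
Title: Vertical Connectivity of Total and Active Marine Prokaryotic Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of paired 16S rDNA (total) and 16S rRNA
    (active) amplicon count tables sampled along an ocean water column.
    Provides repeated rarefaction, 16S copy-number correction, centred
    log-ratio (Aitchison) beta-diversity with PERMANOVA and NMDS, alpha and
    phylogenetic diversity with nonparametric group tests, log2 RNA:DNA
    activity ratios, first-detection depth categorisation of amplicon
    sequence variants (including phantom taxa), detection and
    classification of RNA-abundance shifters, surface-taxon fate
    (active/inactive/lost) and rarity/occurrence classification, and a
    synthetic paired-survey generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    picante,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
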