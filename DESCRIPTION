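Package: aonsnp
Title: All-or-None SNP Analysis for Replicated Selection Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing allele-frequency divergence between replicated
    selection lines and their unselected controls, built around the
    "all-or-none" SNP concept: loci fixed for the same allele in every
    replicate line of one selection group while fixed in no replicate line of
    the other group. Provides classification of all-or-none SNPs from per-line
    allele-frequency panels, gap-based genomic clustering of classified loci
    with interval padding, strand-aware gene-proximity annotation
    (upstream/downstream/exon/intron with distances), co-localization of
    differentially expressed genes with SNP clusters, an explicit
    Wright-Fisher neutral-drift null (exact Markov chain and Monte Carlo) for
    the all-or-none pattern, permutation tests for non-random genomic
    distribution and enrichment, and a synthetic-data generator emulating a
    replicated selective-breeding design (4 selected + 4 control lines,
    effective population size about 35, 88 generations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
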