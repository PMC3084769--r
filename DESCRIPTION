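Package: hervclone
Title: Locus Assignment, Molecular Diversity and Tag Profiling for
    HERV-W env Amplicon Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the cellular sources of human endogenous
    retrovirus W (HERV-W) envelope transcripts. Assigns cloned env
    amplicon sequences to their chromosomal encoding loci by pairwise
    identity against a curated paralog reference panel (97% identity
    over at least 580 bp), performs in-silico nested PCR with the
    published SU-TM primer sets, quantifies molecular diversity
    (segregating sites, Watterson-normalised theta, percent divergence
    from the ERVWE1 prototype), estimates Ka/Ks by the Li-Wu-Luo (1985)
    counting method, builds neighbor-joining trees rooted to an
    outgroup, counts short sequence tags against HERV and host gene
    references with housekeeping normalisation, and selects host genes
    co-expressed with HERV-W env by a Pearson r-squared cutoff. A
    synthetic-data module generates paralog panels, clone libraries and
    tag-count matrices with recorded ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
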