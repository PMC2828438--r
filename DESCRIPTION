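Package: rarecodon
Title: Identify Rare Codons from Codon-Pair Preference in Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical identification of rarely-used codons in a bacterial
    coding-sequence set purely from hexamer (codon-pair) preference, without
    any gene-expression reference data. Counts codon pairs in reading frame
    and frame-agnostically, tests each of the 4096 hexamers for
    under-representation with binomial lower-tail probabilities against an
    encoding-rule null and a nucleotide-composition null, classifies pairs as
    rare or normal at a Bonferroni-style cutoff, and ranks the 64 codons by an
    upper-tail hypergeometric enrichment test over the rare-pair group. Also
    provides the per-gene F_rare index (frequency of rare codons) alongside
    the classical CAI, CBI and Fop indices, Spearman and Mann-Whitney rank
    statistics for comparing gene groups, annotation of codon pairs for stop
    codons and restriction-site motifs, and a synthetic coding-sequence
    simulator with controllable codon usage and pair-context suppression for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
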