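Package: trappinevo
Title: Comparative Molecular Evolution of Trappin-Family Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region-partitioned evolutionary analysis of small multigene
    families such as the mammalian trappins. Implements Jukes-Cantor and
    gamma-corrected Tamura-Nei distances with column-bootstrap standard
    errors, modified Nei-Gojobori counting of synonymous and nonsynonymous
    substitutions, Fisher exact tests for regional rate acceleration and
    positive selection, neighbor-joining trees with bootstrap support,
    linearized-tree molecular-clock dating of gene duplications, WAP-domain
    and transglutaminase-substrate repeat scanners, Harr-plot dot matrices,
    genome-assembly quality summaries from cDNA/genomic exon comparisons,
    and a seeded simulator of trappin-like gene families with known truth
    for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
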