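Package: crisprcomb
Title: Comparative Characterization of CRISPR-Cas Systems in Bacterial Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative CRISPR-Cas characterization across bacterial
    genome assemblies and metagenomic read sets: de novo detection of
    repeat-spacer arrays in contigs, direct-repeat typing by edit distance
    against a reference catalog, hairpin folding and tetraloop extraction for
    type I-E repeats, canonical/orphan context labeling by Cas-gene proximity,
    recovery of spacers directly from unassembled paired reads with
    host-read filtering, cross-genome spacer matching with identity
    thresholds and self-hit removal, attribution of spacer matches to
    prophage, genic and intergenic intervals, and Wilcoxon-Mann-Whitney
    comparisons with Monte-Carlo power analysis. Includes a synthetic-data
    generator that plants arrays, prophages, shared spacers and mixed-community
    reads with complete ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
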