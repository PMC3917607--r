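Package: indelscout
Title: Two-Step Indel Detection from Mismatch-Only Alignments in Deep
    Targeted Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small insertions and deletions from deep targeted
    resequencing of short single-end reads by exploiting the alignment
    artifacts of rapid mismatch-only aligners. Step one screens the
    reference for candidate positions using median-normalized depth and
    edge-mismatch tracks combined into an indel detector function; step
    two confirms candidates by Smith-Waterman alignment of the unaligned
    read pool against a short reference segment, requiring a shared gap
    interval across supporting reads. Includes a spike-in read simulator
    with ground-truth bookkeeping, a gapless k-mismatch aligner emulating
    ELAND/MAQ-era tools, zygosity classification and carrier-fraction
    estimation from normalized depth and mismatch features, and
    sensitivity/specificity benchmarking under candidate budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
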