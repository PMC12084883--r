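Package: tailscope
Title: IsomiR Tailing and Poly(A) Tail-Length Analysis for Small RNA and
    Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3'-end analysis of RNA sequencing data: collapsing and
    assigning small-RNA reads to mature miRNAs, classifying isomiR 3' ends as
    canonical, trimmed, non-templated (NT) tailed or ambiguous against
    pri-miRNA genomic context, summarising NT-tail length and nucleotide
    composition, negative-binomial differential accumulation testing with
    median-of-ratios normalisation, per-transcript poly(A) tail-length
    comparison from per-read nanopore tail estimates, and correlation of
    mono(A)-tailed miRNA isoforms with target mRNA expression. Includes a
    ground-truthed synthetic-data generator for every pipeline stage and a
    config-driven end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
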