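Package: rilqtl
Title: QTL Mapping, Recombination Landscapes, and Rearrangement Detection
    in Biparental RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided analysis of biparental recombinant inbred line
    (RIL) populations genotyped with sparse, error-prone markers such as
    genotyping-by-sequencing. Provides heuristic marker curation and
    imputation, physically scaled window-pair recombination matrices that
    reveal chromosome rearrangements (pseudo-linkage between chromosomes and
    recombination suppression within them), single-marker QTL scans with
    permutation-derived genome-wide significance thresholds and fall-off
    support intervals, candidate-gene co-location tests (exact binomial and a
    density-aware bootstrap null), and a seeded RIL meiosis simulator with
    planted QTLs and optional translocation/inversion rearrangements for
    validating every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    scales,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
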