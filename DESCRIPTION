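Package: haplopaint
Title: Ancestry Painting and Diversity Statistics for Supergene Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based local ancestry painting of phased haplotypes against
    reference panels, with a rank-sum significance gate, a greedy heuristic that
    repairs statistical-phasing switch errors by relabelling ancestry tracts,
    windowed population-genetic summary statistics (nucleotide diversity, dXY,
    net divergence da, Hudson's FST), linkage-disequilibrium r-squared, and
    recombination-breakpoint classification against a map of rearranged
    supergene modules. Includes a Balding-Nichols style simulator that generates
    phased cohorts with planted recombinant mosaics, phase-switch errors and
    missing data, together with exact truth tables for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    withr,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
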