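Package: argscan
Title: Genealogy-Based Selective Sweep Scans for Island Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects population-specific selective sweeps from series of
    local genealogies (ancestral recombination graph output) using
    hypergeometric species enrichment scores and the relative TMRCA-half
    statistic (RTH'), with empirical outlier thresholds calibrated on
    control windows. Also provides the classic windowed summary statistics
    (nucleotide diversity, Tajima's D, Weir-Cockerham FST, Garud's
    H1/H2/H12 with haplotype merging), site filtering for resequencing
    panels, a two-population isolation-with-migration coalescent simulator
    with hard and soft sweeps for calibration and power analysis, and a
    lineage-count-through-time feature encoder for genealogy-based
    selection inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
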