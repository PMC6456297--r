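Package: epipersist
Title: Tile-Based Analysis of Histone-Mark Redistribution and Heritable
    DNA-Methylation Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for studying how a germline chromatin
    perturbation redistributes a repressive histone mark and leaves DNA
    methylation changes that persist into offspring somatic tissue.
    Provides fixed-width genome tiling with BED/bedGraph/coverage-table
    readers, input-subtracted ChIP tile signal with replicate-consistent
    changed-tile calling and metagene profiles, tile-based differential
    DNA methylation from per-CpG bisulfite counts with variant masking
    and cluster thinning, sperm-to-soma persistence classification with
    hypergeometric overlap enrichment, distance- and overlap-based
    feature association, PWM motif enrichment, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
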