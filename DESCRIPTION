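Package: txchromdyn
Title: Transcription and Chromatin Dynamics from Interval-Level Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidyverse-native toolkit for characterising RNA polymerase II
    promoter-proximal pause release, UV-triggered transcription elongation
    waves, nascent-RNA intron retention, and nucleosome organisation from
    interval-level sequencing data (read/fragment BED intervals, peak sets,
    and count tables). Implements promoter escape-index (EI) calculations and
    peak-based gene-activity classification, a two-state left-to-right Poisson
    hidden Markov model for elongation wave-front calling and speed estimation,
    pulse-chase intron retention ratios with an IQR-trimmed resampling
    permutation test, and ATAC-seq Vplot construction, dyad calling, fuzziness
    and nucleosome-spacing analysis. Ships seeded synthetic-data generators
    with ground truth for every analysis so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    IRanges,
    S4Vectors,
    stats,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
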