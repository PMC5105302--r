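Package: chassiskit
Title: Genetic-Tool Characterization for the Cyanobacterial Chassis
    Synechococcus sp. PCC 7002
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for characterizing genetic tools in
    the marine cyanobacterium Synechococcus sp. PCC 7002: discovery of
    candidate neutral integration sites as large unannotated intergenic
    gaps in a genome annotation, transformation-efficiency quantification
    (cfu per fmol of integration fragment, corrected by PCR-screen positive
    fractions), reporter-fluorescence promoter characterization (wild-type
    normalization, OD-matched linear interpolation, strength tiers, and
    regulatory-pattern classification), diurnal qRT-PCR relative
    quantification by the 2^-ddCT method with signed fold-change
    conventions, and a synthetic-data generator that plants known ground
    truth for every pipeline stage so parameter recovery can be tested
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomeInfoDb,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
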