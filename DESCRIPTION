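Package: thalascreen
Title: Maternal Alpha-Thalassemia Deletion Carrier Screening from cfDNA Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects maternal carriers of the common alpha-globin (HBA) cluster
    deletions (--SEA, --THAI, --FIL, -a3.7, -a4.2) from targeted cell-free DNA
    sequencing coverage. Counts aligned cfDNA fragments over a 66-bin tiling of
    the ~21 kb HBA cluster, normalizes counts with the transcripts-per-million
    (TPM) scheme, and classifies samples with a two-stage random-forest
    ensemble (normal/abnormal, then four-way subtyping of abnormals). Includes
    a negative-binomial cfDNA coverage simulator for the study conditions, a
    Hardy-Weinberg/Punnett population-burden calculator, and one-vs-rest
    performance metrics.
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
    ranger,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
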