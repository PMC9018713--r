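Package: imagingtx
Title: Imaging Transcriptomics of Parcellated Brain Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links regional gene expression (Allen Human Brain Atlas style
    microarray data parcellated to a Desikan-Killiany style atlas) to
    parcellated PET radiotracer binding maps. Implements probe selection by
    differential stability, signed weighted gene co-expression network
    analysis with topological overlap and module eigengenes, partial least
    squares decoding of tracer maps with a spatial-autocorrelation-preserving
    spin permutation null and bootstrap gene-weight ranking, and weight-based
    gene-set (cell-type) enrichment. A synthetic-data module generates every
    input the pipeline consumes with known ground truth, so the full analysis
    runs and is validated without any downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
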