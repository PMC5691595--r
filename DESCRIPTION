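Package: herbnetpharm
Title: Network-Pharmacology Screening of Herbal Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-style pipeline for network-pharmacology screening of
    herbal compound libraries: filters compounds by predicted oral absorption
    (HIA and Caco-2 class calls), ranks them by an accuracy-weighted signed
    CYP450-inhibition score, predicts protein targets for new chemical
    entities by degree-normalised resource diffusion over a
    substructure-drug-target network, classifies targets by expression in
    keratinocytes and melanocytes, runs hypergeometric gene-set
    over-representation with Benjamini-Hochberg control, and builds and
    exports compound-target interaction networks for Cytoscape. A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads; a 2^-ddCt helper quantifies qRT-PCR readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    withr,
    jsonlite
Config/testthat/edition: 3
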