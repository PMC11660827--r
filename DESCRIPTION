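Package: generescue
Title: Rescue-Gene Classification for Three-Group RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes dysregulated by a disease condition and restored
    ("rescued") by a drug treatment in three-group bulk RNA-seq designs
    (control / disease / disease+drug). Implements a dual-caller
    differential-expression consensus, two rescue-classification strategies
    (a DE-based "normalized" criterion and a five-rule abundance /
    confidence-interval-overlap procedure), hypergeometric GO term
    over-representation with common-child-term identification on the ontology
    DAG, a negative-binomial study simulator with planted gene classes for
    recovery benchmarking, and derived-quantity computations for companion
    wet-lab assays (mitochondrial stress-test OCR parameters,
    lactate/glucose stoichiometry, delta-delta-Cq relative expression, LDH
    release, per-protein normalization, and robust outlier screening).
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
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    edgeR,
    S4Vectors
Config/testthat/edition: 3
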