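Package: qscrosstalk
Title: Longitudinal Quorum-Sensing Cross-Talk Networks from Time-Series
    Metagenomic Gene Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, longitudinal quorum-sensing (QS) cross-talk
    networks from time-series metagenomic gene catalogs of assembling
    microbial communities, such as in vitro oral biofilm succession models.
    Provides a QS reference protein database model, Smith-Waterman homology
    retrieval under BLAST-style identity/coverage/e-value thresholds with a
    conserved-domain annotation filter, gene-length and recA single-copy-gene
    abundance normalization, succession-phase classification of QS pathways,
    construction of directed genus-to-genus signal networks with
    forward/reverse cross-talk labels, QS hub identification, and qualitative
    prediction of signal-interference outcomes. A synthetic succession
    community generator with planted QS genes supplies ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
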