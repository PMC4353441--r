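Package: lnclink
Title: Permutation-Tested lncRNA-mRNA Co-Expression Networks for
    Low-Dose Radiation Transcriptomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline linking radiation-responsive long
    noncoding RNAs (lncRNAs) to coding mRNAs in a small-n microarray
    design: per-sample 75th-percentile shift normalization of log2
    intensities, differential-expression calling by unpaired Student's
    t-test with fold-change gating, exclusion of an estrous-cycle variable
    gene signature, permutation-based significance of Pearson correlations
    over experimental-group mean vectors (seeded Monte-Carlo and exact
    exhaustive modes), and bipartite lncRNA-mRNA network construction with
    threshold-robustness summaries. Includes a synthetic-data generator
    with planted strain effects, radiation responses and lncRNA-to-mRNA
    coupling, plus truth tables, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
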