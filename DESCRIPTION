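Package: fphc
Title: Gene Regulatory Network Reconstruction by Flooding-Pruning Hill-Climbing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns discrete Bayesian network structures from categorical
    expression data with a two-phase neighbour selection step followed by
    score-based search. The flooding phase locates a breakpoint in each
    gene's sorted mutual-information profile to separate related from
    unrelated genes; the pruning phase ranks related genes by their DPI
    (data processing inequality) Level and cuts indirect relations; a
    BDeu-scored greedy hill climb restricted to the selected neighbour
    sets then orients the edges. Includes an exact-distribution oracle
    for small networks, forward sampling, synthetic benchmark generators,
    and structural evaluation metrics (sensitivity/specificity of
    neighbour selection, edge F-score, SHD on CPDAGs, undirected SHD).
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
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
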