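Package: prophagescan
Title: Prophage Prediction in Bacterial Genomes by Phage-Gene Density Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects prophages in annotated bacterial genomes from the density
    of phage-like genes. Coding sequences are translated and matched against a
    phage protein reference database; genes with significant hits are counted
    in a sliding window (10 kb window, 1 kb step), windows with at least eight
    phage-like genes are merged into preliminary predictions, and borders are
    refined to the outermost phage-like genes and nearby tRNA integration
    sites. Includes a local phage-protein database builder with an
    ABC-transporter exclusion filter, a length-based benchmarking statistic
    (sensitivity and positive predictive value over base-pair overlap with a
    gold standard), and a seeded synthetic-genome generator so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
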