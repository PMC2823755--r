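Package: rnafour
Title: RNA Secondary-Structure Folding with a Four-Russians Speedup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers for the basic RNA-folding problem: the maximum-score
    non-crossing matching of complementary nucleotides in an RNA sequence.
    Provides the classic O(n^3) dynamic program in both the diagonal and
    column evaluation orders, a Four-Russians accelerated O(n^3/log n)
    variant with interleaved lookup-table precomputation, an exponential
    brute-force oracle for verification, traceback to an optimal matching,
    and dot-bracket / connectivity-table (CT) structure output. Includes a
    benchmark and comparison harness and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    yaml,
    optparse,
    Biostrings,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
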