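Package: apsp
Title: All-Pairs Suffix-Prefix Overlaps via a Balanced-Parentheses Suffix Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes, for every ordered pair of sequences in a set, the
    length of the longest suffix of one that equals a prefix of the other --
    the all-pairs suffix-prefix (APSP) problem at the heart of
    overlap-layout-consensus genome assembly.  All sequences are concatenated
    with per-sequence separators into one text; a generalized suffix tree is
    built from the suffix array and LCP array and navigated through its
    balanced-parentheses (BP) representation.  Two algorithms are provided
    (a two-pass scan with per-node candidate lists and per-string stacks,
    and a single leaf-order scan driven by the LCP array), together with two
    space-optimized variants, two parallel work-decomposition strategies
    with output identical to the sequential runs, a brute-force reference
    solver, and synthetic read-set generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    optparse,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
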