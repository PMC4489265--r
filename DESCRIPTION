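Package: sansearch
Title: Suffix Array Neighborhood Search for Protein Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fast protein similarity search by suffix array neighborhood
    voting. A FASTA protein database is indexed into a suffix array; every
    suffix of a query is located by binary search and lexicographic
    neighbors cast votes for database proteins, accumulated over diagonal
    bands. Candidates are ranked by banded Smith-Waterman local alignment
    with Karlin-Altschul e-values, under four search protocols (verifast,
    fast, slow, verislow) that trade candidate-pool depth for speed. Includes
    tabular, BLAST-like and stacked-alignment reports, a seeded synthetic
    benchmark generator with implanted homologs at controlled percent
    identity, and a full dynamic-programming reference for sensitivity
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
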