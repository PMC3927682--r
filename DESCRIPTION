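Package: allmapr
Title: All-Mapping of Short Reads with Q-Gram Prefix Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An all-mapper for short DNA reads: it reports every mapping
    location of a read within a Hamming or edit distance threshold, not just
    the best one.  Candidate locations are generated from an inverted index of
    overlapping q-grams of the reference using count filtering and an
    additional-prefix-gram filter (k+2 non-overlapping grams, at least two
    matching lists), with an indel-aware singleton-pair relaxation.  Candidates
    are verified by Hamming comparison or banded semi-global alignment over a
    two-window heuristic, and results are written as SAM records with CIGAR
    strings.  Includes a read simulator with recorded ground truth and a
    full-sensitivity brute-force oracle mapper for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
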