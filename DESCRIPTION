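Package: pms8
Title: Exact Planted (l,d)-Motif Search with Consensus-Distance Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact solver for the planted (l,d)-motif search problem: given n
    DNA or protein sequences, report every l-mer that occurs within Hamming
    distance d of some window in each sequence. Implements the PMS8 strategy,
    a hybrid sample-driven/pattern-driven search over a stack of candidate
    l-mers with in-place matrix filtering, consensus-total-distance pruning,
    a necessary-and-sufficient existence test for common d-neighbors of three
    l-mers with a constructive witness, and common-neighborhood enumeration
    by pruned depth-first traversal. Includes a planted-instance simulator,
    closed-form expectations for spurious motif counts and challenging
    instance parameters, brute-force reference searches, a process-level
    dynamic work queue, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
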