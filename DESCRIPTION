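Package: ecorrect
Title: Consensus-Based Substitution Error Correction for Short Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Corrects substitution errors in short sequencing reads by hashing
    reads into k-mer buckets, selecting overlapping neighbor reads under a
    Hamming-distance threshold, and replacing bases by a weighted per-column
    consensus in which reads found to be error-free ("perfect" reads) carry
    extra weight. Includes the closed-form probability calculations that guide
    parameter choice (false-candidate bounds, k-mer match probabilities,
    consensus error tails), a truth-tracked read simulator with uniform
    substitution errors, and the standard corrector evaluation metrics
    (sensitivity, specificity, gain, erroneous base assignment, cumulative
    Hamming distance, mapped-read fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
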