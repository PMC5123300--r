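Package: dcmsa
Title: Divide-and-Conquer Multiple Sequence Alignment with HMM Ensembles and
    Consensus Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scaling expensive multiple sequence alignment methods
    to large nucleotide datasets by divide-and-conquer. Implements guide-tree
    centroid-edge decomposition with pluggable subset aligners, profile-profile
    merging of adjacent subset alignments and transitivity merging into a full
    alignment; an ensemble-of-profile-HMMs backbone-extension stage in which
    each query sequence is aligned with its best-bitscore model; a
    posterior-decoding consensus that compresses a sample of alignments into
    the maximum-weight compatible column set; an indel-aware sequence
    evolution simulator (GTR + gamma rates + insertion/deletion events) that
    produces leaf sequences together with the true alignment and model tree;
    and the standard evaluation suite (sum-of-pairs precision/recall, total
    column score, Robinson-Foulds error, paired one-sided tests with
    Benjamini-Hochberg correction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
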