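Package: ehmmalign
Title: Multiple Sequence Alignment of Length-Heterogeneous Datasets with
    Ensembles of Profile HMMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns large, length-heterogeneous sequence datasets by first
    aligning a backbone of full-length sequences, then hierarchically
    decomposing the backbone tree at centroid edges into an ensemble of
    profile hidden Markov models, and finally inserting each remaining
    (possibly fragmentary) query sequence through the HMM it most likely
    originated from, selected by adjusted bit-scores under fast Hierarchical
    or EarlyStop search. Per-query extended alignments are merged by
    transitivity into one alignment. Includes a built-in progressive
    backbone aligner, a glocal profile-HMM engine, sum-of-pairs error
    (SPFN/SPFP) evaluation, and a sequence simulator with a fragmentation
    procedure for constructing high-fragmentary test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
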