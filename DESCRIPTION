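Package: cbpatterns
Title: Distributed Sequence Patterning of Compositionally Biased and
    Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyzers for the distributed sequence properties of
    intrinsically disordered and compositionally biased (low-complexity)
    protein regions. A binomial probability-minimization scanner labels
    single- and multiple-residue compositional biases; pooled scans across
    parameter grids are reduced to optimized compositional modules and
    boundary sets; sets of same-bias bands are scored for evenness as a
    distance to perfect banding against random endpoint nulls; residue
    segregation (blockiness), homopeptide content, and interval-entropy
    repetitiveness are each scored against composition-preserving scrambled
    nulls with empirical p-values and z-scores. A toy-sequence generator
    (tandem repeats, residue blocks, alternating bands, uniform-random)
    supports calibration and property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Proteomics
RoxygenNote: 7.3.3
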