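Package: olca
Title: Overlap-Layout-Consensus Assembly of Long Reads with Rank-Based
    Minimizer Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An overlap-layout-consensus assembler for long sequencing reads.
    Overlaps are detected with minimizers hashed from a fixed-array 15-mer
    spectrum so that single-copy k-mers (counts at the spectrum mode) are
    preferred over repeat-like k-mers. The undirected overlap graph carries
    two vertices per read; layout edges are selected by reciprocal-best safe
    edges plus greedy augmentation in decreasing order of a log-likelihood
    score fitted on the safe edges. Consensus contigs are polished with pileup
    majority calls and local de Bruijn reassembly of indel-active regions.
    Diploid read sets are phased with a ReFHap-style minimum-error-correction
    heuristic and reassembled after cross-haplotype graph edges are removed.
    Includes a long-read simulator, a minimizer reference aligner, spectrum
    based substitution error correction, and assembly / alignment / phasing
    benchmark statistics (Nx curves, alignment RMSE, k-mer-based switch-error
    counting).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = FALSE)
Collate: 
    'RcppExports.R'
    'consensus.R'
    'evaluation.R'
    'layout.R'
    'spectrum.R'
    'minimizer.R'
    'olca-package.R'
    'overlap_graph.R'
    'phasing.R'
    'seqio.R'
    'simulate.R'
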