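Package: lssurface
Title: Exact Solution Surface of the Li-Stephens Haplotype Copying Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes, in a single pass over the data, every Viterbi decoding of
    the Li-Stephens haplotype copying model as the recombination penalty sweeps
    its whole range, for both a focal haplotype and an unphased diplotype
    against a template panel. The core is an exact integer-lattice lower convex
    hull dynamic programme: switch/mismatch cost points are propagated site by
    site, so the penalty axis is partitioned into regions with provably
    constant optimal decodings and exact rational breakpoints. Includes slow
    reference decoders (fixed-penalty Viterbi, exhaustive enumeration, direct
    mismatch-table dynamic programming) for validation, a self-contained
    mosaic panel simulator with an optional msprime coalescent hook, and the
    downstream genotype imputation and phasing accuracy experiments (minor
    allele frequency masking, nearest-flanking-marker imputation, Hamming and
    inverse-variance-weighted losses, switch error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
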