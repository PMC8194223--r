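Package: ssuvar
Title: Variability Mapping of Small-Subunit rRNA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Site-specific variability analysis of aligned small-subunit
    (18S) rRNA sequences. Implements TIGER relative site rates from
    site-pattern congruence, uncorrected-p and GTR maximum-likelihood
    pairwise distances with group-wise summaries, hypervariable-region
    (V1-V9) annotation, constant/variable site classification, indel-run
    and deletion-motif characterization, a nonparametric test battery for
    rate differences between structural categories, constrained
    secondary-structure transfer with pseudoknot layers, and a seeded
    three-clade sequence simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
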