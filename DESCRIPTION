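Package: lahr
Title: Design of Sticky-End Repair Templates for AsCas12a Genome Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing precise genome-editing reagents that exploit
    the staggered, 5'-overhang-generating cut of AsCas12a. Scans loci for TTTV
    PAM target sites on both strands, models the two-nick cut geometry (18th or
    19th base after the PAM on the non-target strand), and constructs
    ligation-assisted homologous recombination (LAHR) templates combining one
    sticky end with one PAM-proximal homology arm, cut-and-paste (CAPR)
    double-sticky-ended replacement inserts, and single-stranded ODN donors for
    comparison. Includes codon-aware silent PAM/seed disruption, heuristic
    candidate scoring and ranking, orderable-oligo output, a deterministic
    synthetic-locus and amplicon-read simulator, and quantification of editing
    outcomes from amplicon reads via global alignment and the
    edited-over-total-reads efficiency statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
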