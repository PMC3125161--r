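Package: pdeform
Title: Coarse Flexible Protein Structure Alignment and Score Significance
Version: 0.1.0
Authors@R:
    person("pdeform", "maintainers", email = "pdeform@example.org",
           role = c("aut", "cre"))
Description: Flexible pairwise protein structure alignment in the ProtDeform
    style: backbones are partitioned into short secondary-structure-pure
    fragments, each fragment pair carries its own optimal rigid (Kabsch)
    transformation fitted over a spatial neighbourhood, and an iterated
    block-constrained dynamic programming step refines the residue
    correspondence until convergence.  The similarity of a pair is summarised
    by the length-normalised PD-score in [0,1].  A companion statistics
    toolkit calibrates score significance: sliding gapless alignments as a
    null model, extreme-value (Gumbel) fits, context-specific empirical
    P-values, Bayesian posterior fold/homology probabilities with
    phase-transition thresholds, type I/II error curves, and
    length-dependence regressions.  A synthetic-structure generator (ideal
    helices, strands, hinge-rotated domain pairs, simulated score samples)
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
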