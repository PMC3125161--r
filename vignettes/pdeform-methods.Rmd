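---
title: "Flexible structure alignment and score significance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible structure alignment and score significance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdeform)
```

## The problem

Rigid-body structure comparison fails on proteins that move: a hinge
rotation between two domains can leave every local piece of structure
intact while making the global superposition poor.  `pdeform` aligns two
C-alpha backbones *flexibly*: the chains are cut into short
secondary-structure-pure fragments, and each fragment pair carries its
own optimal rigid transformation, fitted over a spatial neighbourhood.
The aligner alternates a block-constrained dynamic programming (DP)
matching step with transformation refitting until the matching is
stable.  The similarity of a pair is summarised by the PD-score in
[0, 1], and a companion toolkit turns scores into calibrated statistical
statements (P-values, posterior class probabilities, decision
thresholds).

## The model and the iteration

**Sites and fragments.**  A structure is an ordered list of C-alpha
coordinates with per-site secondary-structure labels (H/E/C).  Labels
are partitioned into fragments inside each maximal run of one label:
with `k = min(9, sites remaining)`, a full look-ahead (`k = 9`) emits a
fragment of 6 (leaving at least 3 behind), otherwise one fragment of `k`
sites.  Most fragments therefore have length 6, all lie in 3..9, and
runs shorter than 3 appear as-is.  The neighbourhood `N_m(F)` of a
fragment is the `m` sites closest to it in space (site-to-fragment
distance = distance to the nearest fragment site); the fragment's own
sites, at distance 0, are always included.

**Local transformations.**  Given a matching, each fragment pair (F, G)
containing a matched pair receives the Kabsch least-squares rotation +
translation fitted over the matching restricted to `N_m(F) x N_m(G)`.
Fewer than three such pairs make the transformation *undefined* — a
distinguishable value, not an error, because scoring falls back to the
global whole-matching superposition.

**Scores.**  Distances become similarities through
`simterm(d^2) = 1 / (1 + d^2 / d0)` with `d0 = 11.5`; score-matrix
entries are `simterm(d^2) - kappa` with `kappa = 2 * simterm(81)`, and
the DP's per-unmatched-site penalty is `simterm(81) / 2`.  These three
constants are calibrated so that the net gain of matching a pair at
distance d equals `simterm(d^2) - simterm(81)`: positive exactly below
9 Å, the distance beyond which a matched pair is considered poor.  The
published equation bodies for the score term, penalty and final score
are not fully legible in our source material; the forms above are this
package's own calibrated surrogates, and every constant is exposed in
`pd_config()`.

**Dynamic programming.**  The DP maximises
`F = sum S(i,j) - penalty * ((L1 - Na) + (L2 - Na))` over
order-preserving one-to-one matchings in which every matched site lies
in a diagonal run of at least 6 consecutive matches (adjacent blocks
merge before the length check).  Internally the equivalent per-pair-gain
form `sum (S + 2*penalty)` is optimised — the two differ by exactly
`penalty * (L1 + L2)` on every alignment, and that identity is asserted
in the tests.  Ties on the objective prefer more matched pairs, then a
fixed deterministic backtracking order, so repeated runs are
byte-identical.

**Iteration and convergence.**  Initialise the score matrix, then repeat
DP → local transforms → rescore.  The loop stops when the matching
repeats the previous one, when any previously seen matching recurs (a
cycle — the best PD-score seen is kept), or after `max_steps = 30`.
Arguments are ordered canonically inside (shorter first, ties by id), so
the result is exactly symmetric under argument swap.

**PD-score.**  `PD = sum simterm(d_ij^2) / ((L1 + L2) / 2)` over matched
pairs, with distances taken under the fragment-pair transformations.
The symmetric `(L1+L2)/2` denominator bounds the score in [0, 1] and
gives self-alignments exactly 1; `min(L1, L2)` and `sqrt(L1*L2)`
normalisations are selectable.  The score is computed as a division so
the self-score is exact in floating point.

## The initial score matrix

The original method seeds the iteration from a structure-environment
classifier whose substitution tables are not public.  The surrogate used
here combines a secondary-structure match indicator with the similarity
of intra-chain distance profiles `d(i, i±k), k = 1..4` (clamped at chain
ends): `s0 = w_sse * match + w_prof / (1 + delta2 / d0_prof) - kappa`
with `w_sse = w_prof = 0.5`, so initial entries span the same
`[-kappa, 1-kappa]` range as rescored entries.  This choice only seeds
the first DP pass; the iteration replaces it with distance-based scores
from step two onward.

## Secondary structure

The source method does not say how SSEs were assigned, and fragment
boundaries depend on it.  The default is a C-alpha-only geometric rule
in the P-SEA style: each window tests d(i,i+2), d(i,i+3), d(i,i+4)
against helix bands (5.0–6.0, 4.8–5.8, 5.8–7.0 Å) and strand bands
(6.1–7.3, 8.5–10.8, 11.3–13.8 Å), labels the window centre, and demotes
helix runs shorter than 4 and strand runs shorter than 3 to coil.  The
rule is purely distance-based, hence exactly invariant under rigid
motion.  `assign_sse()` also accepts HELIX/SHEET records or externally
computed (e.g. DSSP) labels, which is the recommended route when
reproducing results that are sensitive to fragment boundaries.

## Gapless null model and significance

For prediction-quality significance the null is the population of
*gapless* alignments: the shorter domain slid along the longer one in
leaps of 20 residues (plus a C-terminal-aligned extra window), each
window scored under the identity correspondence.  Window scores are
fitted with a maximum-likelihood Gumbel (EVD type I) law; `fit_gumbel`
centres the data internally, making the fit exactly shift-equivariant,
and reports a coefficient of determination of expected vs observed bin
frequencies (bin width 0.005).  Fragments are recomputed on each window
(labels from the full chain): the window is the object being scored.
Whether the original method recomputed them is unknown; the choice is
configuration-visible.

Three contexts get three different P-values: gapless (prediction
scoring), optimised alignments under a different-fold null, and under a
different-homology null.  Empirical P-value curves are raw
right-continuous survival functions on a 0.001 grid; posterior curves
apply Bayes' rule to add-one-smoothed binned densities (bin 0.01) of
same/diff score samples under a user-supplied prior.  There is
deliberately no default prior: the fold-level prior in the literature
comes from an external database cross-mapping, and
`priors_from_mapping()` computes one from any two-scheme mapping by
counting agree-in-both vs disagree-in-both domain pairs (pairs agreeing
in exactly one scheme are excluded).

The *phase-transition threshold* is the smallest grid score whose
posterior reaches 0.5 and stays there for the next 5 populated grid
points (an anti-noise guard; benchmark-scale curves are smooth but small
samples are not).  A curve that starts at or above 0.5 has no
transition and is an error.  The threshold report carries the a priori
errors (type I = P-value of the threshold on the diff sample, type II =
`P(S < s* | same)`) and the prior-weighted a posteriori errors
`P(diff | S >= s*)` and `P(same | S < s*)`.

Length dependence is measured as in the source study: records grouped by
exact length, per-length mean scores regressed on length by weighted
least squares with the per-length counts as weights (so the regression
is weighted by length frequencies), optionally restricted to the
discriminant high-score range first.  Exact-length grouping was chosen
over interval binning; with the frequency weights the two agree closely
on large samples.

## The synthetic world

The generator exists so that every operation is testable without
downloads; its geometry constants are textbook values, not claims about
the source data:

* `make_helix`: rise 1.5 Å/residue, radius 2.3 Å, 100°/residue —
  consecutive C-alpha spacing ≈ 3.8 Å, d(i,i+3) ≈ 5.05 Å.
* `make_strand`: planar zig-zag with exact 3.8 Å spacing and 6.6 Å
  d(i,i+2).
* `make_domain`: seeded sequential placement of segments with random
  inter-segment orientations, 3.0 Å self-clash check with retry,
  optional Gaussian jitter.
* `make_hinge_pair`: a copy with all sites beyond a hinge rotated about
  a random axis through the hinge C-alpha — identity correspondence,
  known ground truth for flexible alignment.
* `sample_scores`: different-class scores Gumbel(0.058, 0.027) by
  default (the published gapless-null fit), same-class scores Normal,
  both truncated into (0, 1) by resampling.

What a green test does *not* establish: ideal-geometry helices carry
none of the curvature, fraying and packing irregularity of real
structures, loop conformations are random walks, and the simulated
score populations are unimodal by construction.  Agreement with the
published benchmark numbers (thresholds near 0.33/0.47, error tables,
regression slopes) additionally depends on parameters the source leaves
open (the neighbourhood size m, the exact equation bodies, the original
initialisation tables) and on multi-million-pair external datasets, and
is therefore out of desk-scale scope.

## Numerical choices and degenerate inputs

* Kabsch: SVD with determinant sign correction; always a proper
  rotation, even for degenerate (collinear/planar) inputs, where the
  minimiser may be non-unique.  Under three points: undefined sentinel.
* DP ties: more pairs first, then a fixed candidate order — outputs are
  deterministic, the specific tie-break is implementation-defined.
* Structures shorter than the minimum block: empty alignment, PD 0 — a
  valid result, not an error.
* Altloc: first-listed kept; first model only unless requested;
  insertion codes preserved in residue ids; 1-based indices in R, author
  numbering in outputs.
* P-value lookup is a step function (value at the largest grid point not
  exceeding the query); scores below the grid return 1.

## Known limitations

* The neighbourhood size `m = 40` is a documented guess (the original
  value is withheld as a training-set tuning); results near fragment
  boundaries can differ from the original implementation.
* The initial score matrix is a surrogate; on structures with little
  regular secondary structure the first DP pass is weakly informed and
  more iterations may be needed.
* mmCIF is not parsed; only C-alpha traces are modelled; TM-scores are
  ingested, never computed.
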