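# pdeform

Flexible pairwise protein structure alignment with calibrated score
significance.

## What it is for

Structural biologists comparing two protein domains face two linked
questions: *how similar are the structures* when parts of them have
moved relative to each other (hinge and shear motions defeat a single
rigid superposition), and *what does a similarity score mean* — is 0.33
good evidence that two domains share a fold?  `pdeform` answers both:

1. **Flexible alignment.**  Each backbone is partitioned into short
   secondary-structure-pure fragments (length 3–9, mostly 6).  Every
   fragment pair carries its own optimal rigid (Kabsch) transformation,
   fitted over the `m` spatially nearest sites of each fragment.  A
   block-constrained dynamic programming step (matched sites must sit in
   diagonal runs of ≥ 6) and transformation refitting alternate until
   the matching is stable.  The DP maximises

   ```
   F = Σ_{(i,j)∈π} S(i,j) − penalty · [(L1 − Na) + (L2 − Na)]
   ```

   with `S(i,j) = 1/(1 + d²/d0) − κ`, `d0 = 11.5`, `κ = 2/(1 + 81/d0)`,
   so a matched pair pays off exactly when its transformed distance is
   below 9 Å.  Similarity is summarised by the PD-score

   ```
   PD = Σ_{(i,j)∈π} 1/(1 + d_ij²/d0)  /  ((L1 + L2)/2)   ∈ [0, 1],
   ```

   symmetric in the two structures and 1 for self-alignments.

2. **Score significance.**  A sliding gapless-alignment null (leaps of
   20 residues plus a C-terminal window), maximum-likelihood Gumbel
   (EVD) fits of null scores, empirical P-value curves for three
   contexts (gapless / fold / homology), Bayesian posterior curves of
   class co-membership with phase-transition thresholds, type I/II
   error curves, top-hit rates, and length-dependence regressions
   weighted by length frequencies.

A synthetic generator (ideal helices/strands, seeded multi-segment
domains, hinge-rotated pairs, simulated score samples) makes the whole
pipeline testable offline.

## Worked example

```r
library(pdeform)

# a 65-residue four-helix toy domain and a copy with an 85-degree
# hinge rotation applied from residue 33 on
d  <- make_domain(list(helix = 14, loop = 3, helix = 14, loop = 3,
                       helix = 14, loop = 3, helix = 14),
                  seed = 42, id = "toyA")
hp <- make_hinge_pair(d, hinge_site = 33, angle = 85, axis_seed = 42)

pd_align(hp$a, hp$b)
#> <pd_alignment toyA vs toyA_hinge: 65 pairs, PD-score 0.7710, 2 iteration(s), converged>
```

All 65 residues are matched despite the hinge: the fragment-local
transformations absorb the rotation.  A single rigid superposition of
the same pair places only 42% of the residues within 5 Å.  The PD-score
of 0.77 (not 1.0) reflects that fragments whose neighbourhoods straddle
the hinge compromise between the two rigid bodies.

Score statistics, on a simulated null (the defaults reproduce the
published gapless-null EVD):

```r
ns <- sample_scores(100, 50000, seed = 42)          # Gumbel(0.058, 0.027) null
g  <- fit_gumbel(ns$score[ns$label == "diff"])
g
#> <gumbel_fit: location 0.0580, scale 0.0272, R2 0.9990, n 50000>
gumbel_pvalue(g, 0.20)
#> [1] 0.005414602        # a gapless score of 0.20 is ~0.5% significant

set.seed(42)
phase_threshold(posterior_curve(rnorm(5e4, 0.5, 0.05),   # same-class scores
                                rnorm(5e4, 0.2, 0.05),   # diff-class scores
                                prior_same = 0.5))
#> <threshold_report [fold]: s* = 0.350, posterior 0.604,
#>   type I 0.001260, type II 0.001680, P(diff|S>=s*) 0.0013, P(same|S<s*) 0.0017>
```

The threshold report finds the phase transition of the posterior at the
analytic equal-density crossing (0.35 for these two Gaussians) and
quantifies both decision error types at that threshold.

## Command line

An executable wrapper is installed under `exec/pdeform`:

```sh
pdeform simulate --what hinge --out toy --seed 11 --angle 70
pdeform align toy_a.pdb toy_b.pdb --out result        # result.tsv + result.json
pdeform gapless toy_a.pdb toy_b.pdb --out windows.tsv --leap 20
pdeform simulate --what scores --out scores.tsv --n-diff 50000 --context gapless
pdeform calibrate scores.tsv --context gapless --out calib.json
pdeform pvalue calib.json --score 0.2
```

Every output embeds the full run configuration; reruns with the same
inputs are byte-identical.

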