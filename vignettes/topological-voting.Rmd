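---
title: "Topological voting for segmentation mask ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological voting for segmentation mask ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topovote)
```

## The fusion problem

An ensemble of n segmentors — cross-validation folds of a CNN, several human
annotators, crowd workers — produces n co-registered masks of one image: hard
masks with per-pixel values in {0, 1}, or soft masks in [0, 1]. The fusion
question is how to combine them into one mask that is, on average, better
than any individual. The working premise throughout is that *most annotators
are relatively good*: errors are small boundary perturbations, while a
minority may be grossly wrong (displaced, spurious, or empty). The package
refuses synthetic ensembles where planted outliers reach half the ensemble,
because no voting scheme can be expected to work there.

Arithmetical voting — per-pixel majority for hard masks, per-pixel mean then
a 0.5 threshold for soft masks — is the baseline. It treats pixels as
independent voters and therefore ignores that a mask is one geometric object:
a badly displaced mask still casts a vote at every pixel.

## Jaccard machinery

All topological methods rest on the Jaccard (IoU) score. For hard masks
`J(A, B) = |A ∩ B| / |A ∪ B|`; for soft masks the min-over-max
generalization `J(U, V) = Σ min(u_ij, v_ij) / Σ max(u_ij, v_ij)`, which
reduces bit-exactly to the hard score on binary values. The Jaccard distance
is `d_J = 1 − J`, a metric on masks. The naive binary accuracy (fraction of
agreeing pixels) is also provided, mainly to illustrate why it is *not* used
for evaluation: with a small object, an empty prediction scores near 1.

Two conventions the literature leaves open:

- **Empty/empty Jaccard.** When both masks are entirely empty, J is 0/0. We
  define J = 1 (distance 0): two empty masks coincide, and — decisive for the
  design — this is the convention under which radius-0 local topological
  voting coincides exactly with per-pixel majority voting, the limit the
  local method is supposed to have. Defining J = 0 there would break that
  identity at background pixels.
- **Thresholds.** Binarization uses `value ≥ t` on the upper branch (default
  t = 0.5), so exact half votes go to foreground; with an even ensemble a
  tied majority vote therefore produces 1.

Soft scores are computed after a piecewise-linear *regularization* of the
sigmoid values: [0, 0.2] → 0, [0.8, 1] → 1, linear (`10(v − 0.2)/6`) in
between. Sigmoid outputs crowd the ends of [0, 1]; truncating the
near-saturated tails stops large areas of faint background activation from
dominating the min/max sums. Regularization is a *scoring* aid only: the
fused output of a soft topological vote is the winner's original mask. The
map fixes 0.5, so 0.5-thresholding before or after regularization agrees
except exactly at the 0.5 level.

## The three voting families

**Global topological voting.** Candidate k receives the total distance
`d_k = Σ_i d_J(S_i, S_k)` (self term included; it adds 0). The mask with the
smallest d_k — equivalently the largest total score `J_k = n − d_k` — wins
and is returned *verbatim*. This is medoid selection under the Jaccard
distance: the output is always one of the inputs, so it inherits their
regularity (connectivity, smooth boundaries) that per-pixel averaging
destroys. All argmin/argmax ties break to the lowest index, a deterministic
rule that keeps permutation tests meaningful.

**Local topological voting.** Global selection is too rigid for objects with
complicated global structure (vessel trees): the best whole-image mask may
still be locally poor. Fixing a radius s, each pixel p runs its own contest
among the n clipped windows `[i−s, i+s] × [j−s, j+s] ∩ image`, and the local
winner contributes its value at p. The radius interpolates between the
families: s = 0 gives majority voting (each window is the pixel itself), and
s ≥ max(h, w) gives the global vote. Border windows are clipped, never
zero-padded — zero padding would inflate union counts at the border and
change scores.

**Hybrid two-round voting.** Round 1 uses the total scores J_k not to pick a
winner but to *exclude losers*: either keep candidates with `J_k ≥ n/H` for a
threshold H > 1 (survivor count varies per input), or keep the n_select
best (survivor count fixed). Round 2 votes arithmetically among survivors.
The endpoints are exact: a keep-all rule reproduces arithmetical voting, and
n_select = 1 reproduces topological voting. If the threshold rule would
exclude everyone, the single best candidate is kept — a vote must produce an
output. With a radius, both scoring and exclusion run per pixel on windows
(the default scope); a `scope = "global"` flag instead applies the global
survivor set, for users who prefer one ensemble-wide exclusion decision.
The weighted arithmetical vote (weights proportional to J_k by default)
covers the softer variant of the same idea: higher ensemble agreement, higher
weight. The J_k-proportional rule is one admissible reading of
"agreement-weighted"; it is a package default, not a canonical formula.

## Numerical design

Scores are computed in double precision and compared exactly; all
tie-breaking is by index, never by tolerance. The optimized local voter must
match the brute-force per-pixel reference (`local_vote_reference`)
*bit-exactly*, which constrains the implementation in two ways:

- Window sums are accumulated by separable shifted addition (a sliding box
  sum that only ever adds the window's own elements, O((2s+1)·N) per pass)
  rather than by summed-area-table prefix differences. Prefix subtraction
  introduces cancellation noise of order 1e-13 precisely in the structurally
  exact cases — an all-zero window must sum to exactly 0, identical windows
  must score exactly 1 — and regularized soft masks are full of exact zeros.
  Those cases produce real-arithmetic ties between candidates, and a
  1e-13 perturbation silently flips the documented lowest-index tie-break.
- Per-candidate totals accumulate in the same order (i = 1…n, plain double
  addition) in both the fast and the reference path.

The 1D/2D simulation winners use the algebraic expansion
`Σ_j (S_i − S_j)² = n S_i² − 2 S_i Σ_j S_j + Σ_j S_j²`, O(n) per candidate
instead of O(n²); the literal double loop is kept in the test helpers as an
independent oracle. The expansion is exact in real arithmetic but rounds
differently, which matters only at real-arithmetic ties — e.g. any n = 2
sample is an exact tie — so the randomized equivalence checks use n ≥ 3,
where continuous draws give distinct totals almost surely.

## The estimator story: why topological voting works

With scalar annotations S_i (mean θ), the arithmetical estimator is the
sample average Σ_n and the topological estimator is
`Y_n = argmin_{S_i} Σ_j (S_i − S_j)²`. The total-distance function
`h(x) = Σ_j (x − S_j)²` is a parabola with vertex Σ_n and symmetric about it,
so Y_n is exactly the sample nearest the sample mean — an identity the suite
checks on every random draw, not just asymptotically. Consequently Y_n
inherits the average's consistency and converges to θ at the √n rate; the
convergence experiment verifies empirically that mean |Y_n − θ| decreases
along n = 10…10⁴ and that mean|Y_n − θ|·√n stays within a small constant
factor across that grid (observed ≈ 1.1–1.3 with 500 replicates; 3 is the
asserted bound).

The two estimators separate on *structured* samples S_i = [x_i, f(x_i)]: the
average's second component is mean f(x), not f(mean x), so for convex f
(Jensen) the average drifts off the curve by a bias that does not vanish
with n, while the topological winner, being a sample, sits exactly on the
curve. With f(x) = x², x ~ U(0, 1), n = 200 and 500 replicates, the
topological estimator's mean Euclidean error to [θ, f(θ)] is about 0.72 of
the average's — the acceptance script recomputes this ratio. This is the
1D/2D cartoon of why whole-mask voting beats per-pixel averaging on masks
with structure.

## The synthetic generator

Since real multi-annotator mask sets come from external datasets, the package
ships a seeded generator emulating three truth regimes: a smooth connected
**blob** (thresholded Gaussian-smoothed noise field at the 80th percentile,
largest connected component; ≈ 20% foreground at 64×64), a filled
**rectangle** (25–60% of each side), and a thin **vessel** tree (correlated
4-connected random walks branching from a common root, 1–2 px wide, < 25%
foreground, connected by construction). Good annotators perturb the truth by
up to 1 px translation, one dilation/erosion with a random disc of radius
≤ 1, and 5% foreground dropout — calibrated so their Jaccard to the truth
stays well above 0.5. Outliers are structural: the truth translated by 35% of
the shorter image side in a random direction (the displacement is kept
comfortably above a quarter of the image so the outlier is unambiguous while
still overlapping plausible image regions), an unrelated truth draw, or an
empty mask. An erosion that would erase the mask entirely is skipped —
annotator noise should degrade an object, not delete it. Hard masks can be
blurred (`soften_mask`, Gaussian σ = 1 by default, clamped to [0, 1]) into
calibrated soft ensembles.

What the generator does *not* emulate: correlated errors between annotators,
intensity-dependent errors (the voters never see the image), multi-object
scenes, and class imbalance beyond the single-object regime. Passing tests
therefore show the voting machinery is correct and behaves as designed on
the stated error model; they do not certify performance on any real dataset.

## Problem sizes and defaults

The randomized suites use mask sizes 6×6–16×16 for metric and equivalence
properties (1000 and 100 seeded cases), 200 ensembles across radii
s ∈ {0, 1, 2, 5} for the oracle equivalence, 10⁴ random sample sets for the
nearest-to-mean identity, 500 replicates per sample size for the convergence
and 2D experiments, and 200 seeded 64×64 blob ensembles (n = 10, 3 shift
outliers) for outlier rejection — sizes at which every property is stable
across seeds while the whole suite stays interactive. Hybrid presets mirror
common practice: H ∈ {1.2, 2, 3, 4}, n_select around n/2; H = 2 (keep
J_k ≥ n/2) is the default used in the outlier-rejection study.

## Limitations

- Global and local voting cost O(n²) pairwise scores; the local voter adds a
  factor proportional to the radius. For very large images or ensembles a
  compiled backend would be the next step.
- Soft-mask PNG I/O quantizes to 8 bits; the text-grid dialect is lossless to
  6 decimals and is preferred for round-tripping soft masks.
- Only 2D single-class masks are supported — no multi-class labels, no 3D
  volumes, and no Hausdorff-type alternatives to the Jaccard distance.
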