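---
title: "Methods: generating and evaluating 2D rotation items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generating and evaluating 2D rotation items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexrot)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The item universe

An item's reference object is a 4 × 4 array of 16 visually distinct
hexominoes — polygons of six edge-joined unit squares. `polyominoes()`
enumerates them by growth from the monomino with canonical-form
de-duplication; under rotations and reflections ("free") there are 35
hexominoes, under rotations only ("one-sided") 60. Canonical form is the
lexicographically smallest translated cell set over the transform group,
which makes shape ids stable across runs. The enumeration is bounded at
size 8 by default purely to guard against accidental exponential calls;
the bound is an argument, not a constant.

The target is the array rotated clockwise by 0–3 quarter turns with one
cell removed along a jigsaw cut. The mechanism behind the published cut
counts (4 per corner cell, 8 per non-corner border cell, 16 per internal
cell) is reconstructed here as a **binary tab model**: every cell edge not
on the outer frame carries an outward or inward semicircular tab, so a
cell with *k* internal edges has 2^*k* cuts. This is the simplest
mechanism that reproduces all the printed counts (4/8/16, hence
4·4 + 8·8 + 4·16 = 144 targets and 576 stimulus:target pairings), and we
adopt it as canonical. Coordinates are (col, row) with the origin at the
top-left and y pointing down, matching screen rendering; "clockwise"
rotation is defined in that frame.

Response sets follow the published recipe: six puzzle-piece options of the
target cell's position class — the correct piece, a near-distractor with
the correct hexomino but a different cut of the same cell, and four
fillers drawn without replacement from the remaining same-class pieces —
plus "don't know" and "correct answer not listed". Both meta options are
always present and never correct: the generator always includes the true
piece, and scoring treats either meta choice as incorrect, consistent
with a dichotomous 2PL model. The near-distractor's wrong cut is uniform
over the cell's other cuts. All six piece options share one display
rotation per item; this keeps the four-way rotation-demand classification
(`NONE`, `STIMULUS_ONLY`, `OPTION_ONLY`, `BOTH`) a pure function of the
stimulus and option rotations.

`generate_pool()` fills an explicit composition specification (counts per
item type, optionally per position class) under the invariant that no two
items share a (stimulus rotation, cell, cut) triple. The `"paper70"`
preset has 12 no-rotation items and 58 rotation-demanding items
(19/19/20). We deliberately do not reproduce the original 304-item
difficulty-targeted down-selection — that required human piloting — and
expose stratified composition instead. A corner-cells-only 70-item preset
is not offered because corner cells admit only 4 rotations × 4 cells × 4
cuts = 64 unique pairings, fewer than 70; pools restricted to corners are
available through the `position_class` column at feasible sizes.

Rendering is monochrome SVG with semicircular tabs of radius 0.2 cell
sides and hexominoes scaled to 70% of their cell — pure aesthetics, fixed
so output is byte-deterministic. The environment for the suite has no SVG
rasterizer, so raster-level invariants (the cut-out region is blank; the
correct option tile patches it back to the full rotated array) are checked
on an integer occupancy grid computed from the same layout geometry the
renderer uses, which makes the reconstruction check exact rather than
anti-aliased.

## The planned-missingness simulator

`sapa_design()` emulates a synthetic-aperture protocol: items-per-person
counts are i.i.d. from a configurable distribution, and the administered
subset is uniform without replacement. The default distribution
{1: 0.45, 2: 0.27, 3: 0.25, 6: 0.03} echoes the reported administration
pattern (close to half of examinees answering a single rotation item, 97%
receiving three or fewer); the original distribution is only partially
characterized in print, so this default is an approximation and is
flagged as such. What the simulator does **not** emulate: self-selection
of web volunteers, non-uniform item sampling weights, answer-option
position effects, or any response process beyond the 2PL — so passing
tests show that the estimators work under the design's missingness, not
that real respondents behave like the model.

`pairwise_counts()` and `min_pairwise_filter()` implement the pairwise
co-administration accounting that such designs live on, with the
published minimum of 500 joint administrations as the default threshold.
`simulate_bifactor()` provides the test bed for structure evaluation: one
general factor plus one of four group factors per item, all orthogonal
standard normals, with admissibility (g² + s² < 1) enforced and optional
threshold dichotomisation. Its population correlation matrix and omega
are available in closed form (`bifactor_sigma()`,
`population_omega_h()`), which is what the recovery tests compare
against.

## The 2PL engine

Calibration is Bock–Aitkin EM on the pure logistic metric (no 1.702
constant), matching the convention of the R IRT software this field
mostly uses, so parameters are directly comparable. Numerical choices:

* quadrature: 61 equally spaced nodes on [−6, 6] with normal weights
  (configurable), shared by calibration and EAP scoring;
* M step: per-item Newton–Raphson on the logit intercept/slope with step
  halving, at most 3 inner iterations per cycle (a generalized EM step);
* convergence: maximum absolute parameter change < 1e−4, at most 500
  cycles; the marginal log-likelihood trace is kept and asserted
  non-decreasing in the tests;
* stability: response probabilities are clamped to [1e−12, 1 − 1e−12] so
  saturated items cannot inject 0 · log 0 into the likelihood, and the
  slope is capped at 25 (far outside the published 0.91–3.21 range);
* missing responses contribute nothing to the likelihood — missing at
  random by design under planned missingness;
* items with no observed variance are excluded with a warning, never
  silently fitted;
* an optional mild log-normal prior on the slope (location 0, scale set
  by `a_prior_sd`) is available for very sparse designs and off by
  default.

Standard errors come from the per-item expected-information Hessian at
convergence with a delta-method transform to (a, b); they ignore
cross-item uncertainty, the usual approximation at these sample sizes.
EAP scores are posterior means under the N(0, 1) prior; a person with no
scoreable responses gets the prior back (θ = 0, se = 1) and a flag.
`rescale_scores()` maps any score vector linearly to sample mean 50 and
SD 10, the reporting convention for this measure family.

Because the published 57-item calibration is distributed separately,
`surrogate_item_bank()` ships a clearly labelled synthetic stand-in:
difficulty and discrimination grids with fixed endpoints (−0.79/1.96 and
0.91/3.21) whose interior values follow beta quantiles with shape
constants solved once so the sample mean and SD match the printed
summaries (0.34/0.68 and 1.76/0.53) to ~1e−8. A fixed decorrelating
permutation pairs the two grids so difficulty and discrimination are not
artificially coupled. The identity of the one removed low-quality item in
the original analysis is unknown; `screen_information_spikes()` offers a
heuristic (flag items whose removal shifts peak test information by more
than 20%), explicitly not the original rule.

## Structure evaluation

For binary items the default association is the ML tetrachoric (bivariate
normal likelihood over the 2 × 2 table, thresholds from the margins, 0.5
continuity correction for empty cells, Gauss–Legendre evaluation of the
bivariate normal CDF); Pearson is the fallback when margins are
degenerate. Which correlation the original analysis used is not stated,
so both are supported and the default documented. Pairwise-complete
matrices are routinely indefinite, so `smooth_correlation()` clips
eigenvalues at 1e−8 and rescales to unit diagonal before factoring.

`efa_minres()` minimises the squared off-diagonal residuals: uniquenesses
are optimised by L-BFGS-B with the analytic envelope gradient of the ULS
objective (the negative residual diagonal), 10 seeded restarts around the
squared-multiple-correlation start, loadings from the reduced matrix's
leading eigenpairs. One identifiability detail: a factor whose salient
loading is confined to a single item contributes nothing to the
off-diagonal fit and its loading is undefined; such factors are collapsed
to zero with the variance returned to the uniqueness, so an identity
matrix yields all-zero loadings rather than an arbitrary one. Oblimin
(quartimin) rotation is a hand-implemented gradient-projection loop — no
installed package provides minres-plus-oblimin — validated in the tests
against exactly structured inputs where the rotated solution is known.
Factor ordering and signs are normalised for stable output.

`schmid_leiman()` fits one higher-order factor to the factor correlations
(for two factors the standard convention γ₁ = γ₂ = √φ₁₂; for more, a
one-factor minres of Φ), then general loading = primary × γ and group
loading = primary × √(1 − γ²). A non-positive factor-correlation manifold
is an error advising orthogonal treatment, not a silent sign flip. With
`Vt = sum(R)`:

ω_h = (Σ gᵢ)² / Vt, ω_t = 1 − Σ ψᵢ / Vt, α = J/(J−1) · (1 − J/Vt).

Per-group omegas use each group's own submatrix. The tests verify the
closed forms (a one-factor structure with loadings 0.8 gives
ω_h = 3.2²/11.68; the equicorrelated four-factor structure gives general
loadings 0.56) to 1e−6 and recovery of the population ω_h within 0.05 at
n = 20,000 continuous observations. The original study's empirical ω_h
values depend on its proprietary-scale data and are out of scope here.

`item_type_factor_check()` asks whether items load dominantly on their
own rotation-demand type's factor: it fits the four-factor oblimin
solution and maximises the matched fraction over all factor-to-type
assignments, so the result is invariant to label and factor order.

## BISCUIT

`best_scales_cv()` re-implements cross-validated best-scales
construction: folds stratified on criterion deciles (the original fold
assignment is not described; stratification removes one source of
variance), training-fold ranking by pairwise-complete correlation,
selection by an absolute-correlation cut (default 0.2) or top-n — both
rules exist in the original tool and the value used for its published
table is not stated — unit weights equal to the sign of the training
correlation, and held-out evaluation. A fold where nothing passes the cut
selects nothing and contributes no composite; there is deliberately no
fall-back to the single best predictor, so pure-noise predictor sets
yield empty or near-empty reports rather than a confidently selected
artefact. The final key applies the same rule to the full sample; the
report gives each predictor's selection frequency (out of k) and the
mean/SD of its training correlations, the layout of the original's
frequency tables.

## Problem sizes and limitations

The suite exercises the engines at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances while remaining desk-scale: full
enumeration oracles up to size-4 polyominoes (with known counts beyond),
2PL recovery on 2,000 × 57 complete data, marginal-probability checks at
n = 50,000, bifactor and factor-structure recovery at n = 20,000, BISCUIT
at n = 10,000 × 50 predictors. Known limitations: no 3PL guessing
parameter (the "don't know" option is simply scored incorrect), no
differential item functioning, a single higher-order factor in the
Schmid–Leiman (no bifactor rotation alternative), and no modelling of
volunteer self-selection in the simulator.
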