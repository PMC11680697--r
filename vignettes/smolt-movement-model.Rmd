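---
title: "Modelling smolt movement past hydropower intakes with smoltsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smolt movement past hydropower intakes with smoltsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltsim)
```

## The problem

Downstream-migrating Atlantic salmon smolts approaching a hydropower plant
tend to travel with the bulk flow, which usually leads to the turbine
intake. Telemetry work has shown that their fine-scale behaviour is richer
than passive drift: flow-aligned swimming alternates with deterministic
bursts away from the flow and with searching behaviour, and the mix is
statistically associated with the local hydraulics. `smoltsim` implements a
model chain that (i) classifies observed track steps into these behaviours,
(ii) fits boosted-tree models for the behaviour probabilities as functions
of the hydraulic predictors, and (iii) replays those probabilities as a
stochastic individual-based model (IBM) over a raster flow field, with
intake-versus-bypass fate accounting against a drift-only baseline.

The guiding trade-off is deliberate simplicity: correlative behaviour
rules over a static 2D hydraulic layer, cheap enough to rerun for many
discharge scenarios, rather than a mechanistically detailed (and slow)
swimming model.

## The river section

A `flow_scenario` is a rectangular raster of square cells (default edge
0.5 m, matching the resolution at which observed movements were defined as
cell-to-cell transitions). Each cell carries `u` (longitudinal velocity,
m/s, positive downstream), `v` (transversal, positive right-to-left bank),
`w` (vertical, positive up) and `TKE` (turbulent kinetic energy, m²/s²).
One vertical layer is used — by default the second plane below the surface,
where smolts typically travel — and no vertical movement is simulated: `w`
and `TKE` act as predictors only. Dry or out-of-channel cells are `NA` in
all four layers and are never entered by simulated fish.

The local flow heading is the bearing of the horizontal resultant of
`(u, v)`. All circular quantities in the package use a single convention:
mathematical "to" bearings, degrees counter-clockwise from the downstream
(+u) axis, in [0, 360). Helper libraries in other toolchains often return
meteorological ("from") directions; anyone refitting against outputs of
such tools must convert accordingly. The interchange format (CSV field
table with 0-based `x_index`/`y_index` plus a JSON metadata sidecar) is
0-based on disk; the R API uses 1-based `(row, col)` matrix indices as is
idiomatic in R. The metadata carries the grid dimensions explicitly so
that dry border rows survive a write/load round trip.

## Step classification

Observed positions (`fish_id, t, x, y`) are mapped to cells; consecutive
positions in the same cell are collapsed, and each transition between
distinct cells becomes one movement step. Steps are labelled with an
angular tolerance of ±20°, a value reflecting the combined uncertainty of
the hydraulic model and the positioning system; empirically, step-to-flow
angular differences concentrate below roughly this value with a long
near-uniform tail, so the threshold separates the flow-aligned mode from
the rest:

* `FOLLOW` if the step heading is within the tolerance of the flow heading
  of the departure cell (the decision is made where the fish is);
* otherwise `DIRECTIONAL` if within the tolerance of the immediately
  preceding step's heading — the reference heading for "maintaining a
  consistent direction" is the previous step, mirroring the simulator's
  keep-the-previous-heading rule;
* otherwise `NONDIRECTIONAL`. The first step of a fish or segment has no
  previous heading and can never be `DIRECTIONAL`.

Two practical rules handle messy tracks: positions outside the active grid
split a track into independent segments (no step spans a gap), and a
configurable maximum displacement between consecutive pings (default 5 m)
breaks segments at implausible jumps. The displacement filter is a
stand-in for ad-hoc outlier removal in the original data processing, whose
exact rule is not documented; it is disclosed in the function reference
and can be disabled with `Inf`. Steps between non-adjacent cells are kept
as single steps (interpolation would invent positions).

`build_datasets()` produces the two training tables: every labelled step
contributes a row to the follow-the-flow table (`y_follow`), while only
non-follow steps with a defined previous heading enter the swim-direction
table (`y_random` = 1 for a fresh heading). The forced-random first step
of a bout carries no information about the redirection probability and is
excluded.

## The behaviour models

Both models are binary gradient-boosted tree ensembles on the four
predictors. Boosting is performed by `xgboost` with a logistic objective;
shrinkage maps to `eta` and tree complexity to `max_depth`, and relative
influence is the ensemble's split-gain attribution normalised to percent.
Tuning follows the conventional protocol for boosted regression trees in
ecology: a grid of learning rates (0.01, 0.025, 0.005, 0.0025, 0.001) by
tree complexities 1–9 (45 combinations), each evaluated by stratified
k-fold cross-validation (k = 10 by default), with the ensemble size chosen
by early stopping on held-out Bernoulli deviance (patience 50, cap 10,000
trees by default). The combination minimising cross-validated deviance
wins; ties break toward higher cross-validated AUC, then fewer trees.

Design notes:

* The original tuning scheme drew ten bootstrapped subsets of 70 % of the
  data; we use standard k-fold, which targets the same selection criterion
  with a conventional, reproducible protocol. Ensemble sizes are therefore
  data-dependent outputs; published tree counts are accepted as
  configuration fixtures (`reference_brt_metrics()`) when replaying a
  reference parameterisation.
* No per-fish random effects are modelled (behaviour probabilities are for
  the average smolt); `fish_id` is retained in the step tables so grouped
  resampling could be added.
* Deviance clips probabilities to [1e-12, 1 − 1e-12]; predictions are
  likewise clipped, so reported probabilities are strictly inside (0, 1).
* AUC is the midrank Mann–Whitney statistic (ties count ½) and refuses
  single-class inputs; both metrics are verified in the tests against
  brute-force oracles (term-by-term summation; exhaustive pair counting).
* Determinism: fixed seed, data and hyperparameters give bit-identical
  fits and predictions (single-threaded boosting).
* A degenerate ensemble that never splits (e.g. constant features) predicts
  the class prevalence; its influence attribution is undefined and is
  reported as uniform (25 % each).

The `AUC` column of a metrics report is the training AUC, the `CV (AUC)`
column the cross-validated one; both are always labelled explicitly since
performance tables in the literature are ambiguous on this point.

## The movement loop

Each simulated smolt starts on an active cell and repeats: decide, move,
check termination.

* **Decide.** Draw Bernoulli(`P(follow)`). On success the heading is the
  local flow heading plus a uniform jitter within ±tolerance and any
  non-follow bout ends. On the first non-follow decision of a bout, a
  random heading is always drawn uniformly from [0, 360) minus the closed
  arc flow ± tolerance (rejection sampling; the result always differs from
  the flow by more than the tolerance). Within a bout,
  Bernoulli(`P(random)`) chooses between a fresh random heading and
  keeping the stored one.
* **Move.** Among the eight neighbours, the active cell whose
  centre-to-centre bearing is circularly closest to the heading is
  entered; exact ties break clockwise-first. If the nearest-bearing
  neighbour is dry the next-best active one is used (the decision log
  stays faithful to the draws); with no active neighbour the track
  terminates (`"stuck"`, fate `undetermined`).
* **Terminate.** Entering an `intake` or `exit_boundary` cell ends the
  track (`exited`; fate `intake` or `bypass`), as does the step budget
  (`max_steps_reached`, fate `undetermined`).

Whether the forced-random rule applies once per bout (a follow decision
re-arms it) or once per fish is ambiguous as usually stated; the package
defaults to per-bout — the literal reading of "first instance of not
following" within each excursion — and exposes `first_random = "per_fish"`
as a switch. Similarly, drift-only mode jitters the heading within
±tolerance at each step by default (`drift_jitter = FALSE` follows the
exact resultant).

Drift-only mode runs the identical decision loop with an internal constant
follow probability of 1, which is why a user-supplied sure-follow stub
model reproduces drift mode bit-for-bit under a shared seed — a property
the tests assert.

Reproducibility: each track runs on its own RNG substream, seeded by a
32-bit mix of the master seed, the start cell and the replicate index, so
cohorts are reproducible and invariant to the ordering of start cells.
For speed, cohort simulation evaluates both models once over all active
cells (a probability raster per model) rather than per step; the per-step
`decide_step()` draws the identical RNG sequence.

There is no explicit time step: one iteration is one ~0.5 m cell
transition, and swimming speed is not modelled. The default release design
is four start cells with five replicates each (20 smolts) and a budget of
1000 steps per smolt.

## The synthetic channel and truth rules

Because the original telemetry and CFD rasters are not redistributable,
`make_channel_field()` builds a parametric channel: a parabolic downstream
profile (peak 0.8 m/s mid-channel by default — the order of magnitude
smolts encounter in such reaches), a transversal component combining a
smooth meander (amplitude 0.15 m/s) with a Gaussian-windowed pull toward a
lateral intake opening, small seeded vertical-velocity noise, and a TKE
proxy scaled (0.05 m²/s²) with cross-channel shear and lateral flow. The
meander matters for testability: without it `v` would be a pure function
of the cross-channel coordinate — collinear with the parabolic `u` along
most tracks — and influence attribution between the two would be
arbitrary. Banks are dry; the most downstream column is the exit boundary;
the intake is a short row-range at one column.

Ground truth is logistic in the four predictors (with an optional `v × TKE`
interaction to exercise depth > 1): by default the transversal velocity
dominates the follow rule and TKE dominates the redirection rule, echoing
the influence ordering reported for field-fitted models.
`generate_truth_tracks()` drives the same movement loop with these rules
and emits both positions (one ping per cell transition, 5 s apart,
mirroring a typical tag burst interval) and the hidden per-step labels and
probabilities.

What the generator does *not* emulate: positioning error (points are exact
cell centres), missed detections, hydraulic structure beyond the smooth
channel (recirculation zones, wakes), individual heterogeneity, and any
vertical behaviour. Passing recovery tests therefore demonstrates the
pipeline's internal consistency — classification, fitting and simulation
invert the generator — not field validity on real rivers.

One quantisation effect deserves note: simulated headings are continuous
but realised moves snap to eight neighbour bearings, so re-classifying
generated positions mislabels steps whose drawn heading falls within a few
degrees of the 22.5° quantisation boundaries. On an axis-aligned field
(zero lateral flow) this affects well under 1 % of steps, and the
round-trip test asserts ≥ 99 % agreement on the follow split. On fields
with arbitrary flow headings the effect is larger; parameter-recovery
tests therefore fit on the generator's hidden labels (emitted for exactly
this purpose), keeping the calibration check free of quantisation label
noise.

## Evaluation

`track_metrics()` quantifies trajectory complexity: path length, net
displacement, sinuosity (path/net; `NA` for closed tracks), mean absolute
per-step heading change, and the fraction of cells visited more than once
— the diagnostics of searching behaviour. `compare_cohorts()` tabulates
fates and metric summaries across cohorts (behaviour, drift-only,
optionally observed tracks), and `matched_simulation()` replays an
observed track's initial conditions (start cell, step budget) with
simulated replicates, the per-individual comparison design. Statistical
significance testing between cohorts is deliberately out of scope.

## Problem sizes and numerical choices in the test suite

The test and acceptance runs use deliberately small configurations chosen
as adequate for their statistical purpose: oracle checks on ~200 random
instances; simulator properties on channels of roughly 10–50 × 20–60
cells with tens of tracks; calibration recovery on ~320 fish × ≤250 steps
(≈ 25,000 steps), tuned with a reduced single-combination grid and fitted
with early stopping, where the regression of predicted on true follow
probabilities is required to have slope in [0.8, 1.2]; the full 45-way
grid is exercised at smoke scale (300 rows, small tree caps) where only
the search structure, not the metric values, is under test. The
end-to-end pipeline run caps ensembles at ~120 trees; all scientific
defaults (tolerance, grids, k) are left untouched there.

## Known limitations

* Behaviour depends only on the four hydraulic predictors of the occupied
  cell; no memory beyond the stored heading, no biotic factors, no
  swimming speed, no depth choice.
* The constant-depth, single-layer assumption means results speak to one
  horizontal plane of the water column.
* Boosted-tree behaviour models fitted to such data show moderate
  overfitting (cross-validated deviance well above training deviance);
  simulations outside the hydraulic range of the training data are
  extrapolations and should be treated as such.
* Fate accounting is purely geometric (region masks); physical screening,
  predation and mortality are not modelled.
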