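# smoltsim

Spatially explicit individual-based simulation of downstream-migrating
Atlantic salmon smolts (*Salmo salar*) in river reaches around hydropower
intakes.

When smolts migrate to sea they must pass hydropower plants, where the main
flow typically leads toward the turbine intake. Telemetry studies show that
smolts do not drift passively: they follow the flow much of the time, but
also burst away from it in a consistent direction, or search with frequent
heading changes, and these behaviours are associated with the hydraulic
conditions they experience. `smoltsim` turns that observation into a
predictive tool for fish-passage management: it fits behaviour-probability
models to observed tracks and replays them as a stochastic movement model
over any gridded flow field, so that intake-versus-bypass outcomes can be
explored for alternative discharge scenarios or structural measures before
they are built.

## The model

A river reach is a raster of square cells (0.5 m by default), each carrying
one horizontal layer of a CFD solution: longitudinal velocity `u` (m/s,
positive downstream), transversal velocity `v` (positive right-to-left
bank), vertical velocity `w` (positive up) and turbulent kinetic energy
`TKE` (m²/s²). The horizontal resultant of `(u, v)` defines the local flow
heading.

Each observed cell-to-cell movement step is classified with a ±20° angular
tolerance:

* **follow-the-flow** — step heading within 20° of the flow heading;
* **directional deviation** — not following the flow, but within 20° of the
  previous step's heading (a deterministic burst);
* **non-directional deviation** — a fresh heading (searching).

Two binary gradient-boosted tree models are then fitted on the
departure-cell hydraulics `(u, v, w, TKE)`:

1. the **Follow-the-flow model**, `P(follow | u, v, w, TKE)`, over all
   steps;
2. the **Swim-direction model**, `P(new random heading | u, v, w, TKE)`,
   over within-bout deviation steps only.

Hyperparameters (shrinkage ∈ {0.01, 0.025, 0.005, 0.0025, 0.001}, tree
complexity 1–9, ensemble size by early stopping) are selected by k-fold
cross-validation on Bernoulli deviance, with AUC reported alongside.

The simulator (one loop iteration = one cell transition) draws, in each
cell, Bernoulli(`P(follow)`): on success the smolt takes the flow heading
jittered within ±20°; on the first failure of a bout it always draws a
random heading outside the flow ± 20° arc; within a bout,
Bernoulli(`P(random)`) chooses between a fresh random heading and keeping
the stored one. The smolt then moves to the nearest-bearing active
neighbour, and the loop ends at an intake or exit-boundary cell (fate:
`intake` vs `bypass`) or at the step budget. A drift-only baseline (always
follow the flow ± 20°) and track-complexity metrics (sinuosity, heading
change rate, revisit fraction) support evaluation against observed tracks.

Because the original telemetry and CFD data are available on request only,
the package ships a synthetic channel generator with known logistic
behaviour rules, used throughout the tests to verify that the whole
pipeline recovers known truth.

## Worked example

```r
library(smoltsim)

## a synthetic reach with a lateral intake, and tracks from known rules
scenario <- make_channel_field(synthetic_field_spec(n_rows = 40, n_cols = 60, seed = 1))
gen      <- generate_truth_tracks(scenario, truth_params(), n_fish = 60,
                                  max_steps = 200, seed = 2)

## classify observed positions into behaviour steps
labeled <- label_steps(cellize_track(gen$points, scenario), tolerance = 20)
table(labeled$behaviour)
#>         FOLLOW    DIRECTIONAL NONDIRECTIONAL
#>           2871            501           1353

## tune + fit the two behaviour models
ds     <- build_datasets(labeled)
cv     <- tune_brt(ds$follow_table, lr_grid = c(0.05, 0.01), depth_grid = c(2, 3),
                   k = 5, seed = 3, max_trees = 300, patience = 20)
follow <- fit_brt(ds$follow_table, cv$best, seed = 3)
follow
#> <smolt_brt> follow_the_flow: depth 3, shrinkage 0.05, 116 trees, n = 4725
#>   influence: v 58.6%, tke 32.2%, w 5.2%, u 4.0%
cv_d      <- tune_brt(ds$direction_table, lr_grid = c(0.05, 0.01),
                      depth_grid = c(2, 3), k = 5, seed = 3,
                      max_trees = 300, patience = 20)
direction <- fit_brt(ds$direction_table, cv_d$best, seed = 3)

## release 4 x 5 smolts and compare with the drift-only baseline
starts <- list(c(8, 2), c(16, 2), c(24, 2), c(32, 2))
beh   <- simulate_cohort(scenario, follow, direction,
                         sim_config(starts, replicates_per_start = 5,
                                    max_steps = 1000, seed = 4))
drift <- simulate_cohort(scenario,
                         config = sim_config(starts, replicates_per_start = 5,
                                             max_steps = 1000, seed = 4,
                                             mode = "drift_only"))
cmp <- compare_cohorts(list(behaviour = beh, drift_only = drift), scenario)
cmp$fate_table
#>       cohort         fate  n proportion
#> 1  behaviour       intake  5       0.25
#> 2  behaviour       bypass 15       0.75
#> 3  behaviour undetermined  0       0.00
#> 4 drift_only       intake  1       0.05
#> 5 drift_only       bypass 19       0.95
#> 6 drift_only undetermined  0       0.00
```

The fitted follow-the-flow model ranks the transversal velocity `v` as the
most influential predictor (58.6 %), matching the dominant slope of the
generating rule. The behaviour cohort is markedly more tortuous than the
drift baseline (mean sinuosity 2.25 vs 1.08; mean per-step heading change
61° vs 12°), and its fates differ: searching behaviour carries more smolts
into the intake's zone of influence than pure drift does.

The same pipeline is available from a shell via the installed `smoltsim`
script (`exec/smoltsim`) with subcommands `synth`, `classify`, `fit`,
`simulate` and `evaluate`; every run writes a JSON run log with the seed
and a config hash.

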