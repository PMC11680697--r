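#' Specification for a synthetic channel flow field
#'
#' Parametric stand-in for one horizontal layer of a hydrodynamic model of a
#' river reach with a lateral turbine intake: a parabolic downstream
#' velocity profile across the channel, a smooth transversal component
#' drawing flow toward the intake, small random vertical velocities, and a
#' shear-based turbulent kinetic energy proxy. The first and last rows are
#' dry banks. Magnitudes default to the range smolts encounter in the
#' studied reaches (downstream velocities up to about 1 m/s, TKE up to a
#' few hundredths of a m^2/s^2).
#'
#' @param n_rows,n_cols grid dimensions (at least 5 each; defaults 40 x 60).
#' @param base_speed peak downstream velocity, m/s (default 0.8).
#' @param cross_flow_amplitude amplitude of a smooth lateral meander
#'   component, m/s (default 0.15). The meander varies along the channel,
#'   so the transversal velocity is not a pure function of the
#'   cross-channel position; without it `v` would be collinear with the
#'   parabolic `u` profile along most tracks.
#' @param intake_rows integer row range of the intake opening (default
#'   rows 2:6, along one bank).
#' @param intake_col column of the intake opening (default at three
#'   quarters of the reach).
#' @param intake_attraction strength of the lateral pull toward the intake
#'   relative to `base_speed` (dimensionless, default 0.4; 0 disables it).
#' @param tke_scale scale of the turbulent kinetic energy proxy, m^2/s^2
#'   (default 0.05).
#' @param seed RNG seed for the vertical-velocity noise.
#' @return list of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(n_rows = 40L, n_cols = 60L, base_speed = 0.8,
                                 cross_flow_amplitude = 0.15,
                                 intake_rows = 2:6, intake_col = NULL,
                                 intake_attraction = 0.4, tke_scale = 0.05,
                                 seed = 1L) {
  stopifnot(n_rows >= 5L, n_cols >= 5L, base_speed > 0, tke_scale >= 0)
  if (is.null(intake_col)) intake_col <- as.integer(round(0.75 * n_cols))
  stopifnot(all(intake_rows >= 2L), all(intake_rows <= n_rows - 1L),
            intake_col >= 2L, intake_col < n_cols)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 base_speed = base_speed,
                 cross_flow_amplitude = cross_flow_amplitude,
                 intake_rows = as.integer(intake_rows),
                 intake_col = as.integer(intake_col),
                 intake_attraction = intake_attraction,
                 tke_scale = tke_scale, seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

#' Generate a synthetic channel flow scenario
#'
#' Builds the [flow_scenario()] described by a [synthetic_field_spec()]:
#' `u` is parabolic across the channel (fastest mid-channel, zero at the
#' banks), `v` combines an optional meander with a Gaussian-windowed pull
#' toward the intake rows around the intake column, `w` is small seeded
#' noise, and `tke` scales with the cross-channel shear of `u` plus the
#' lateral-flow magnitude. The `intake` region is the intake row range at
#' the intake column; the `exit_boundary` region is the last (most
#' downstream) column.
#'
#' @param spec a [synthetic_field_spec()].
#' @return a [flow_scenario()] (cell size 0.5 m, layer 2).
#' @export
make_channel_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  s <- (row - 1) / (nr - 1)                       # 0 at one bank, 1 at other
  u <- spec$base_speed * 4 * s * (1 - s)
  r_c <- mean(spec$intake_rows)
  window <- exp(-0.5 * ((col - spec$intake_col) / (0.12 * nc))^2)
  pull <- (r_c - row) / (nr / 2)
  v <- spec$cross_flow_amplitude * sin(2 * pi * (col - 1) / (nc - 1)) *
         4 * s * (1 - s) +
       spec$intake_attraction * spec$base_speed * window * pull
  set.seed(spec$seed)
  w <- matrix(stats::rnorm(nr * nc, 0, 0.02 * spec$base_speed), nr, nc)
  shear <- abs(1 - 2 * s)                          # parabolic-profile shear
  tke <- spec$tke_scale * (0.2 + shear + abs(v) / spec$base_speed)

  dry <- row == 1L | row == nr
  u[dry] <- v[dry] <- w[dry] <- tke[dry] <- NA_real_

  intake <- matrix(FALSE, nr, nc)
  intake[spec$intake_rows, spec$intake_col] <- TRUE
  exitb <- matrix(FALSE, nr, nc)
  exitb[2:(nr - 1L), nc] <- TRUE

  flow_scenario(u, v, w, tke, cell_size = 0.5, discharge_q = NA_real_,
                layer_index = 2L,
                regions = list(intake = intake, exit_boundary = exitb))
}

#' Ground-truth behaviour rules for synthetic smolts
#'
#' Logistic models mapping the four hydraulic predictors to the
#' follow-the-flow probability and to the within-bout random-redirection
#' probability:
#' `p = plogis(intercept + b_u*u + b_v*v + b_w*w + b_tke*tke
#'             + b_vxtke*v*tke)`.
#' The optional `v * tke` interaction exercises tree depth greater than 1
#' in recovery tests. Default coefficients make `v` the dominant driver of
#' following the flow and `tke` the dominant driver of redirection,
#' echoing the influence ordering seen in field-fitted models.
#'
#' @param follow_coefficients named vector `intercept, u, v, w, tke` (and
#'   optionally `vxtke`) for the follow-the-flow rule.
#' @param random_coefficients same structure for the swim-direction rule.
#' @param tolerance angular tolerance the truth simulator uses, degrees.
#' @return list of class `truth_params`.
#' @export
truth_params <- function(
    follow_coefficients = c(intercept = 1.0, u = 0.8, v = -6.0, w = 0.5,
                            tke = -8.0, vxtke = 0),
    random_coefficients = c(intercept = -0.5, u = -2.0, v = 1.0, w = 0.5,
                            tke = 10.0, vxtke = 0),
    tolerance = 20) {
  fix <- function(b) {
    full <- c(intercept = 0, u = 0, v = 0, w = 0, tke = 0, vxtke = 0)
    stopifnot(all(names(b) %in% names(full)), all(is.finite(b)))
    full[names(b)] <- b
    full
  }
  structure(list(follow_coefficients = fix(follow_coefficients),
                 random_coefficients = fix(random_coefficients),
                 tolerance = tolerance),
            class = "truth_params")
}

#' True behaviour probabilities at given hydraulics
#'
#' @param truth a [truth_params()].
#' @param hydraulics named vector or data.frame with `u, v, w, tke`.
#' @return list with vectors `p_follow` and `p_random`.
#' @export
truth_probability <- function(truth, hydraulics) {
  stopifnot(inherits(truth, "truth_params"))
  X <- as_predictor_matrix(hydraulics)
  lin <- function(b) {
    b[["intercept"]] + X[, "u"] * b[["u"]] + X[, "v"] * b[["v"]] +
      X[, "w"] * b[["w"]] + X[, "tke"] * b[["tke"]] +
      X[, "v"] * X[, "tke"] * b[["vxtke"]]
  }
  list(p_follow = unname(stats::plogis(lin(truth$follow_coefficients))),
       p_random = unname(stats::plogis(lin(truth$random_coefficients))))
}

#' Wrap a truth rule as a behaviour model
#'
#' Lets the ground-truth logistic rules drive the simulator through the
#' same [predict_prob()] interface as fitted models.
#'
#' @param truth a [truth_params()].
#' @param which `"follow"` or `"random"`.
#' @return object of class `smolt_truth`.
#' @export
truth_model <- function(truth, which = c("follow", "random")) {
  which <- match.arg(which)
  structure(list(truth = truth, which = which,
                 model_kind = if (which == "follow") "follow_the_flow"
                              else "swim_direction"),
            class = c("smolt_truth", "smolt_behavior_model"))
}

#' @export
predict_prob.smolt_truth <- function(model, hydraulics) {
  p <- truth_probability(model$truth, hydraulics)
  if (model$which == "follow") p$p_follow else p$p_random
}

#' Generate ground-truth smolt tracks
#'
#' Runs the simulator's decision loop with the truth rules in place of
#' fitted models and emits (a) position tracks (cell centres with synthetic
#' timestamps at a fixed ping interval, one cell transition per ping)
#' suitable for [cellize_track()], and (b) the hidden per-step decision
#' labels, departure-cell hydraulics and true probabilities for parameter-
#' recovery and round-trip tests.
#'
#' @param scenario a [flow_scenario()].
#' @param truth a [truth_params()].
#' @param n_fish number of simulated fish.
#' @param start_cells start cells; default: spread across the second column.
#' @param max_steps maximum transitions per fish (default 200).
#' @param seed master seed.
#' @param ping_interval seconds between pings (default 5, a typical acoustic
#'   tag burst interval).
#' @return list with `points` (data.frame `fish_id, t, x, y`), `steps`
#'   (data.frame `fish_id, step, u, v, w, tke, decision, y_follow,
#'   y_random, p_follow, p_random`; `y_random` is `NA` for follow steps and
#'   for the forced-random first step of a bout) and `cohort` (the
#'   underlying `smolt_cohort`).
#' @export
generate_truth_tracks <- function(scenario, truth, n_fish = 20L,
                                  start_cells = NULL, max_steps = 200L,
                                  seed = 1L, ping_interval = 5) {
  stopifnot(inherits(scenario, "flow_scenario"), inherits(truth, "truth_params"))
  if (is.null(start_cells)) {
    rows <- unique(round(seq(2L, nrow(scenario$u) - 1L, length.out = 8L)))
    rows <- rows[cell_active(scenario, rows, rep(2L, length(rows)))]
    start_cells <- lapply(rows, function(r) c(r, 2L))
  }
  starts <- rep(start_cells, length.out = n_fish)
  cfg <- sim_config(start_cells = start_cells, replicates_per_start = 1L,
                    max_steps = max_steps, tolerance = truth$tolerance,
                    seed = seed)
  grids <- model_grids(scenario, truth_model(truth, "follow"),
                       truth_model(truth, "random"), "behaviour")
  pts <- list(); stp <- list(); tracks <- list()
  for (i in seq_len(n_fish)) {
    sc <- starts[[i]]
    set.seed(track_seed(seed, sc[[1]], sc[[2]], i))
    tr <- run_track(scenario, as.integer(c(sc[[1]], sc[[2]])), grids, cfg)
    tracks[[i]] <- tr
    ctr <- cell_center(scenario, tr$cells[, 1], tr$cells[, 2])
    pts[[i]] <- data.frame(fish_id = sprintf("fish%03d", i),
                           t = (seq_len(nrow(ctr)) - 1) * ping_interval,
                           x = ctr[, "x"], y = ctr[, "y"])
    n <- length(tr$decisions)
    if (n > 0L) {
      fr <- tr$cells[seq_len(n), , drop = FALSE]
      dec <- tr$decisions
      # y_random defined only for within-bout decisions: non-follow steps
      # whose previous decision was also non-follow
      in_bout_prev <- c(FALSE, dec[-n] != "FOLLOW")
      stp[[i]] <- data.frame(
        fish_id = sprintf("fish%03d", i), step = seq_len(n),
        u = scenario$u[fr], v = scenario$v[fr],
        w = scenario$w[fr], tke = scenario$tke[fr],
        decision = dec,
        y_follow = as.integer(dec == "FOLLOW"),
        y_random = ifelse(dec != "FOLLOW" & in_bout_prev,
                          as.integer(dec == "NONDIRECTIONAL"), NA_integer_),
        p_follow = grids$p_follow[fr], p_random = grids$p_random[fr])
    }
  }
  fates <- factor(vapply(tracks, `[[`, "", "fate"),
                  levels = c("intake", "bypass", "undetermined"))
  cohort <- structure(list(tracks = tracks, fate_counts = table(fates),
                           mode = "behaviour", config = cfg),
                      class = "smolt_cohort")
  list(points = do.call(rbind, pts), steps = do.call(rbind, stp),
       cohort = cohort)
}

#' Training tables from ground-truth step labels
#'
#' Counterpart of [build_datasets()] operating on the generator's hidden
#' labels instead of classified ones; used for parameter-recovery tests
#' free of grid-quantisation label noise.
#'
#' @param steps the `steps` element of [generate_truth_tracks()].
#' @return list of `follow_table` and `direction_table`.
#' @export
truth_datasets <- function(steps) {
  pred <- c("u", "v", "w", "tke")
  follow_table <- cbind(steps[, pred], y_follow = steps$y_follow)
  dir <- steps[!is.na(steps$y_random), , drop = FALSE]
  direction_table <- cbind(dir[, pred], y_random = dir$y_random)
  rownames(follow_table) <- rownames(direction_table) <- NULL
  list(follow_table = follow_table, direction_table = direction_table)
}
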